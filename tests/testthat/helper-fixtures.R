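# Shared fixtures: everything is generated in code at test time.

# Small cohort spec that keeps volumes tiny but the class structure intact.
tiny_spec <- function(n_subjects = 8, seed = 101, ...) {
  cohort_spec(n_subjects = n_subjects, class_balance = 0.5,
              volume_shape = c(20L, 20L, 20L), tumor_radius_range = c(3, 4),
              seed = seed, ...)
}

# Equal focus fractions in both classes: a cohort with no genotype effect.
null_focus <- function(h = 0.15, p = 0.10) {
  list(wildtype = c(hypermetabolic = h, perfusion = p),
       mutant = c(hypermetabolic = h, perfusion = p))
}

# Deterministic single-compartment spec: all compartments share one mean,
# no between-subject jitter, no latent field, no voxel noise.
flat_spec <- function(mean = c(2, 2, 2, 2, 1.5, 1), noise_sd = 0, seed = 5) {
  flat <- lapply(default_compartment_params(), function(p) {
    p$mean[] <- mean; p$sd[] <- 0; p
  })
  cohort_spec(n_subjects = 4, class_balance = 0.5, volume_shape = c(16L, 16L, 16L),
              compartment_params = flat, noise_sd = noise_sd, latent_sd = 0,
              tumor_radius_range = c(2, 3), seed = seed)
}

# Build a study directly from arrays (bypasses the generator).
array_study <- function(channels_list, brain, tumor, genotype = "wildtype",
                        age = 50, id = "subA") {
  new_study(id, channels_list, brain, tumor, genotype, age)
}

# A study whose six channels are filled from a single array (or constant).
uniform_study <- function(value = 1, shape = c(8L, 8L, 8L), brain = NULL,
                          tumor = NULL, ...) {
  vol <- if (length(value) == 1) array(value, shape) else value
  if (is.null(brain)) brain <- array(TRUE, shape)
  if (is.null(tumor)) {
    tumor <- array(FALSE, shape)
    tumor[3:4, 3:4, 3:4] <- TRUE
  }
  channels <- stats::setNames(rep(list(vol), 6), gliosom_channels())
  array_study(channels, brain, tumor, ...)
}

# Hand-built label-ratio feature table from a ratios (percent) matrix.
make_table <- function(ratios, genotype, age = NULL) {
  n <- ncol(ratios)
  if (is.null(age)) age <- rep(50, n)
  ids <- sprintf("s%02d", seq_len(n))
  colnames(ratios) <- ids
  rownames(ratios) <- paste0("label_", seq_len(nrow(ratios)))
  structure(list(K = nrow(ratios), ratios = ratios,
                 log_ratios = log_ratio(ratios), subject_ids = ids,
                 genotype = genotype, age = age),
            class = "label_ratio_table")
}

# Two well-separated classes in feature space: class decides which label
# dominates the tumor. `spread` is the within-class noise scale; at small
# spread the class margin survives even single-subject training sets.
separable_table <- function(n_per_class = 5, K = 4, seed = 3, spread = 2) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    ratios <- matrix(0, K, n)
    for (j in seq_len(n)) {
      main <- if (j <= n_per_class) 1 else 2
      w <- abs(stats::rnorm(K, sd = spread)) + 1
      w[main] <- w[main] + 60
      ratios[, j] <- 100 * w / sum(w)
    }
    make_table(ratios, rep(c("wildtype", "mutant"), each = n_per_class))
  })
}

# A small trained SOM + partition over structured random features.
tiny_som <- function(n = 300, grid = c(4L, 4L), seed = 42) {
  withr::with_seed(seed, {
    centers <- matrix(stats::runif(6 * 3), 3, 6)
    X <- t(centers[sample(3, n, replace = TRUE), ] + matrix(stats::rnorm(n * 6, 0, 0.05), n, 6))
    train_som(X, grid_shape = grid, epochs = 10)
  })
}
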