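#' Specification of a synthetic multiparametric cohort
#'
#' Defines the study conditions emulated by the generator: a balanced-ish
#' two-genotype glioma cohort in which wild-type tumors carry larger
#' hypermetabolic (high-FDOPA) and high-perfusion (high-rCBV) sub-volumes
#' than mutant tumors, T2WI and ADC share a latent field (hence correlate
#' positively inside the brain), and wild-type patients are older.
#'
#' Intensities are in arbitrary units; voxel values are clamped at zero
#' because magnitude MRI and SUV data are nonnegative.
#'
#' @param n_subjects number of subjects.
#' @param class_balance fraction of wild-type subjects, in (0,1). The default
#'   reproduces a 33:29 wild-type:mutant composition at `n_subjects = 62`.
#' @param volume_shape integer 3-vector of voxel counts per axis.
#' @param compartment_params named list (`normal_brain`, `tumor_bulk`,
#'   `hypermetabolic_focus`, `perfusion_focus`), each a list with `mean` and
#'   `sd` numeric 6-vectors in channel order ([gliosom_channels()]). `sd` is
#'   the between-subject variability of the compartment mean.
#' @param focus_fraction_by_class named list (`wildtype`, `mutant`) of
#'   numeric vectors `c(hypermetabolic =, perfusion =)`: expected fraction of
#'   tumor voxels assigned to each focus. Per class the fractions must sum
#'   to at most 1.
#' @param noise_sd per-channel additive voxel noise SD (6-vector or scalar).
#' @param latent_sd SD of the latent field shared by the T2WI and ADC
#'   channels (drives their positive correlation).
#' @param age_params named list (`wildtype`, `mutant`) of `c(mean =, sd =)`
#'   in years.
#' @param tumor_radius_range 2-vector, tumor sphere radius range in voxels.
#' @param brain_radius_frac brain sphere radius as a fraction of the smallest
#'   volume dimension.
#' @param seed integer cohort seed; identical spec + seed gives a
#'   bit-identical cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 62,
                        class_balance = 33 / 62,
                        volume_shape = c(48L, 48L, 48L),
                        compartment_params = default_compartment_params(),
                        focus_fraction_by_class = list(
                          wildtype = c(hypermetabolic = 0.15, perfusion = 0.10),
                          mutant   = c(hypermetabolic = 0.03, perfusion = 0.02)),
                        noise_sd = rep(0.3, 6),
                        latent_sd = 0.25,
                        age_params = list(wildtype = c(mean = 59, sd = 12),
                                          mutant   = c(mean = 46, sd = 12)),
                        tumor_radius_range = c(6, 10),
                        brain_radius_frac = 0.45,
                        seed = 1L) {
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 6)
  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         class_balance = class_balance,
         volume_shape = as.integer(volume_shape),
         compartment_params = compartment_params,
         focus_fraction_by_class = focus_fraction_by_class,
         noise_sd = as.numeric(noise_sd),
         latent_sd = as.numeric(latent_sd),
         age_params = age_params,
         tumor_radius_range = as.numeric(tumor_radius_range),
         brain_radius_frac = brain_radius_frac,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default compartment intensity parameters
#'
#' Mean/SD per channel (arbitrary units) for the four tissue compartments.
#' Tumor bulk is T2/FLAIR/ADC-bright relative to normal brain; the
#' hypermetabolic focus is FDOPA-dominant with reduced ADC; the perfusion
#' focus is rCBV-dominant.
#'
#' @return Named list of compartments, each `list(mean =, sd =)`.
#' @export
default_compartment_params <- function() {
  ch <- GLIOSOM_CHANNELS
  mk <- function(mean, sd) list(mean = stats::setNames(mean, ch),
                                sd = stats::setNames(rep(sd, 6), ch))
  list(
    #                 cet1   t2  flair  adc  rcbv fdopa
    normal_brain         = mk(c(2.0, 2.0, 2.0, 2.0, 1.5, 1.0), 0.15),
    tumor_bulk           = mk(c(2.5, 4.0, 4.5, 3.5, 2.0, 1.5), 0.20),
    hypermetabolic_focus = mk(c(3.5, 3.5, 4.0, 2.0, 2.5, 5.0), 0.30),
    perfusion_focus      = mk(c(3.0, 3.5, 4.0, 2.5, 5.0, 2.0), 0.30)
  )
}

#' Validate a `cohort_spec`
#' @param spec object to check.
#' @return `spec` invisibly, or an error.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!(spec$class_balance > 0 && spec$class_balance < 1))
    stop("class_balance must lie in (0,1)")
  if (length(spec$volume_shape) != 3L || any(spec$volume_shape < 4L))
    stop("volume_shape must be a 3-vector of voxel counts (>= 4)")
  comp_names <- c("normal_brain", "tumor_bulk", "hypermetabolic_focus",
                  "perfusion_focus")
  if (!all(comp_names %in% names(spec$compartment_params)))
    stop("compartment_params must define: ", paste(comp_names, collapse = ", "))
  for (nm in comp_names) {
    p <- spec$compartment_params[[nm]]
    if (length(p$mean) != 6L || length(p$sd) != 6L)
      stop("compartment '", nm, "' needs 6-channel mean and sd")
    if (any(p$sd < 0)) stop("compartment '", nm, "' has negative sd")
  }
  for (cls in c("wildtype", "mutant")) {
    f <- spec$focus_fraction_by_class[[cls]]
    if (is.null(f) || !all(c("hypermetabolic", "perfusion") %in% names(f)))
      stop("focus_fraction_by_class$", cls,
           " must name hypermetabolic and perfusion fractions")
    if (any(f < 0) || sum(f) > 1)
      stop("focus fractions for ", cls, " must be >= 0 and sum to <= 1")
  }
  if (any(spec$noise_sd < 0) || spec$latent_sd < 0) stop("noise SDs must be >= 0")
  if (diff(spec$tumor_radius_range) < 0 || spec$tumor_radius_range[1] <= 0)
    stop("tumor_radius_range must be increasing and positive")
  invisible(spec)
}

# Squared distance of every voxel to a center, as a 3-D array.
dist2_to <- function(shape, center) {
  dx <- (seq_len(shape[1]) - center[1])^2
  dy <- (seq_len(shape[2]) - center[2])^2
  dz <- (seq_len(shape[3]) - center[3])^2
  outer(outer(dx, dy, "+"), dz, "+")
}

#' Generate one synthetic subject
#'
#' Draws, in a fixed order from the stream `seed`: the subject's age, the
#' per-compartment mean intensities, the tumor radius and center, the focus
#' centers, the shared T2/ADC latent field, and per-channel voxel noise.
#' The tumor is a sphere inside an eroded brain mask; each focus is the
#' connected blob of tumor voxels nearest a random seed voxel, sized to the
#' class-conditional expected fraction of tumor voxels.
#'
#' @param spec a [cohort_spec()].
#' @param genotype `"wildtype"` or `"mutant"`.
#' @param seed integer stream seed for this subject.
#' @param subject_id identifier stored in the study.
#' @return A `synthetic_subject`: list with `study` (a `gliosom_study`) and
#'   `compartment_map` (integer array; 0 background, 1 normal brain, 2 tumor
#'   bulk, 3 hypermetabolic focus, 4 perfusion focus).
#' @export
generate_subject <- function(spec, genotype, seed, subject_id = "sub001") {
  validate_cohort_spec(spec)
  genotype <- match.arg(genotype, c("wildtype", "mutant"))
  shape <- spec$volume_shape
  with_rng(seed, {
    ap <- spec$age_params[[genotype]]
    age <- max(18, stats::rnorm(1, ap["mean"], ap["sd"]))

    comp_names <- c("normal_brain", "tumor_bulk", "hypermetabolic_focus",
                    "perfusion_focus")
    subj_mean <- t(vapply(comp_names, function(nm) {
      p <- spec$compartment_params[[nm]]
      pmax(0, stats::rnorm(6, p$mean, p$sd))
    }, numeric(6)))
    rownames(subj_mean) <- comp_names
    colnames(subj_mean) <- GLIOSOM_CHANNELS

    r_tum <- stats::runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
    too_big <- which(2 * r_tum + 1 > shape)
    if (length(too_big))
      stop("tumor radius ", round(r_tum, 2), " exceeds volume bounds along dimension ",
           paste(too_big, collapse = ", "))

    center <- (shape + 1) / 2
    r_brain <- spec$brain_radius_frac * min(shape)
    r_feasible <- r_brain - r_tum - 1
    if (r_feasible < 0)
      stop("tumor radius ", round(r_tum, 2),
           " does not fit inside the brain mask (brain radius ", round(r_brain, 2), ")")

    d2_center <- dist2_to(shape, center)
    brain <- d2_center <= r_brain^2

    # tumor center: uniform over the eroded brain ball (rejection sampling)
    repeat {
      off <- stats::runif(3, -r_feasible, r_feasible)
      if (sum(off^2) <= r_feasible^2) break
    }
    tum_center <- round(center + off)
    tumor <- dist2_to(shape, tum_center) <= r_tum^2
    tumor <- tumor & brain

    comp <- array(0L, dim = shape)
    comp[brain] <- 1L
    comp[tumor] <- 2L

    # foci: nearest-`target` tumor voxels around a random in-tumor seed
    tum_idx <- which(tumor)
    n_t <- length(tum_idx)
    fr <- spec$focus_fraction_by_class[[genotype]]
    tum_xyz <- mask_coords(tumor)
    place_focus <- function(avail, target) {
      if (target == 0L || !length(avail)) return(integer(0))
      seed_i <- avail[sample.int(length(avail), 1L)]
      d2 <- colSums((t(tum_xyz[avail, , drop = FALSE]) - tum_xyz[seed_i, ])^2)
      avail[order(d2)][seq_len(min(target, length(avail)))]
    }
    avail <- seq_len(n_t)
    hm_loc <- place_focus(avail, round(fr[["hypermetabolic"]] * n_t))
    avail2 <- setdiff(avail, hm_loc)
    pf_loc <- place_focus(avail2, round(fr[["perfusion"]] * n_t))
    comp[tum_idx[hm_loc]] <- 3L
    comp[tum_idx[pf_loc]] <- 4L

    # channel intensities inside the brain; exact zeros outside
    in_brain <- which(brain)
    comp_in <- comp[in_brain]
    latent <- stats::rnorm(length(in_brain), 0, spec$latent_sd)
    channels <- stats::setNames(vector("list", 6), GLIOSOM_CHANNELS)
    for (c_i in seq_along(GLIOSOM_CHANNELS)) {
      ch <- GLIOSOM_CHANNELS[c_i]
      vol <- array(0, dim = shape)
      v <- subj_mean[comp_in, c_i]
      if (ch %in% c("t2", "adc")) v <- v + latent
      if (spec$noise_sd[c_i] > 0)
        v <- v + stats::rnorm(length(v), 0, spec$noise_sd[c_i])
      vol[in_brain] <- pmax(0, v)
      channels[[ch]] <- vol
    }

    study <- new_study(subject_id, channels, brain, comp >= 2L, genotype, age)
    structure(list(study = study, compartment_map = comp),
              class = "synthetic_subject")
  })
}

#' Generate a synthetic cohort
#'
#' Genotype counts follow `class_balance` with deterministic rounding
#' (`round(n_subjects * class_balance)` wild-type subjects). Each subject is
#' generated from its own counter-derived stream, so the cohort is
#' reproducible regardless of generation order.
#'
#' @param spec a [cohort_spec()].
#' @return List with `subjects` (list of `synthetic_subject`), `manifest`
#'   (data.frame: subject_id, genotype, age) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  n_wt <- as.integer(round(n * spec$class_balance))
  n_mut <- n - n_wt
  if (n_wt < 2L || n_mut < 2L)
    stop("need at least 2 subjects per genotype (leave-one-out CV is undefined ",
         "otherwise); got ", n_wt, " wild-type and ", n_mut, " mutant")
  genotype <- rep(c("wildtype", "mutant"), c(n_wt, n_mut))
  ids <- sprintf("sub%03d", seq_len(n))
  subjects <- lapply(seq_len(n), function(i) {
    generate_subject(spec, genotype[i], seed = derive_seed(spec$seed, "subject", i),
                     subject_id = ids[i])
  })
  manifest <- data.frame(
    subject_id = ids,
    genotype = genotype,
    age = vapply(subjects, function(s) s$study$age, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest, spec = spec),
            class = "gliosom_cohort")
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' One NIfTI file per channel and mask per subject. Channels are written as
#' float64 so re-reading reproduces the arrays exactly; masks as uint8.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param overwrite overwrite existing files? Default errors on collision.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "gliosom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- c(GLIOSOM_CHANNELS, "brain", "tumor")
  manifest <- cohort$manifest
  for (v in vols) manifest[[paste0("path_", v)]] <- NA_character_
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]$study
    arrays <- c(s$channels,
                list(brain = s$brain_mask * 1L, tumor = s$tumor_mask * 1L))
    for (v in vols) {
      f <- file.path(dir, paste0(s$subject_id, "_", v, ".nii.gz"))
      if (file.exists(f) && !overwrite)
        stop("file exists (set overwrite = TRUE): ", f)
      dt <- if (v %in% c("brain", "tumor")) "uint8" else "double"
      RNifti::writeNifti(RNifti::asNifti(arrays[[v]]), f, datatype = dt)
      manifest[[paste0("path_", v)]][i] <- f
    }
  }
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf) && !overwrite)
    stop("file exists (set overwrite = TRUE): ", mf)
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return List with `studies` (list of `gliosom_study`) and `manifest`.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  studies <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    channels <- stats::setNames(lapply(GLIOSOM_CHANNELS, function(v) {
      a <- as.array(RNifti::readNifti(row[[paste0("path_", v)]]))
      array(as.numeric(a), dim = dim(a))
    }), GLIOSOM_CHANNELS)
    rd_mask <- function(v) {
      a <- as.array(RNifti::readNifti(row[[paste0("path_", v)]]))
      array(a > 0.5, dim = dim(a))
    }
    new_study(row$subject_id, channels, rd_mask("brain"), rd_mask("tumor"),
              row$genotype, row$age)
  })
  list(studies = studies, manifest = manifest)
}
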