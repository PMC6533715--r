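#' Paired inspiratory/expiratory CT study container
#'
#' Holds voxel-aligned inspiratory and expiratory attenuation grids (HU) and
#' a binary lung mask of the same shape. Registration is assumed done: the
#' two grids are voxel-to-voxel comparable.
#'
#' @param insp_hu,exp_hu Numeric 3D arrays of CT attenuation (HU).
#' @param mask Logical (or 0/1) array of the same shape with at least one
#'   `TRUE` voxel.
#' @return A list of class `paired_ct_study` with elements `insp_hu`,
#'   `exp_hu`, `mask`.
#' @export
paired_ct_study <- function(insp_hu, exp_hu, mask) {
  if (!identical(dim(insp_hu), dim(exp_hu)) ||
      !identical(dim(insp_hu), dim(mask)))
    abort_malformed("inspiratory, expiratory and mask grids must share a shape")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) abort_malformed("mask must be binary")
  if (!any(mask)) abort_domain("mask selects no voxels")
  if (any(!is.finite(insp_hu[mask])) || any(!is.finite(exp_hu[mask])))
    abort_malformed("HU values inside the mask must be finite")
  structure(list(insp_hu = insp_hu, exp_hu = exp_hu, mask = mask),
            class = "paired_ct_study")
}

#' Percent low-attenuation area below a threshold
#'
#' The standard densitometric emphysema/gas-trapping metric: the percentage
#' of masked voxels with attenuation strictly below `threshold_hu`
#' (e.g. -950 HU at inspiration for %LAA-950insp, -856 HU at expiration for
#' %LAA-856exp). Voxels exactly at the threshold are not counted.
#'
#' @param volume_hu Numeric array of attenuation (HU).
#' @param mask Logical array of the same shape.
#' @param threshold_hu Threshold (HU).
#' @return Percentage in \[0, 100\].
#' @export
laa_fraction <- function(volume_hu, mask, threshold_hu) {
  mask <- as.logical(mask)
  if (!any(mask, na.rm = TRUE)) abort_domain("mask selects no voxels")
  vals <- volume_hu[mask]
  100 * sum(vals < threshold_hu) / length(vals)
}

prm_levels <- c("Normal", "fLDA", "pLDA", "Other", "OutsideMask")

#' Parametric response map voxel classification
#'
#' Classifies every masked voxel by the co-registered attenuation pair, using
#' the -950 HU inspiratory and -856 HU expiratory cut-offs:
#' * pLDA (persistent low-density area, emphysematous): insp < -950 and
#'   exp < -856;
#' * fLDA (functional low-density area, non-emphysematous gas trapping):
#'   insp >= -950 and exp < -856;
#' * Normal: insp >= -950 and exp >= -856;
#' * Other: insp < -950 and exp >= -856 (the residual combination, kept in
#'   the denominator but outside the three named classes).
#' Voxels exactly at a cut-off fall on the non-low-attenuation side.
#'
#' @param study A [paired_ct_study()].
#' @return An integer array of the study's shape with levels attribute
#'   `c("Normal","fLDA","pLDA","Other","OutsideMask")`; codes 1-4 inside the
#'   mask, 5 outside.
#' @export
prm_classify <- function(study) {
  if (!inherits(study, "paired_ct_study"))
    study <- paired_ct_study(study$insp_hu, study$exp_hu, study$mask)
  insp_low <- study$insp_hu < -950
  exp_low <- study$exp_hu < -856
  lab <- array(5L, dim = dim(study$mask))
  m <- study$mask
  lab[m & insp_low & exp_low] <- 3L      # pLDA
  lab[m & !insp_low & exp_low] <- 2L     # fLDA
  lab[m & !insp_low & !exp_low] <- 1L    # Normal
  lab[m & insp_low & !exp_low] <- 4L     # Other
  attr(lab, "levels") <- prm_levels
  lab
}

#' Emphysema severity class from %LAA-950insp
#'
#' Stages a study into no / moderate / severe emphysema using the half-open
#' densitometric intervals: NE for %LAA-950insp < 6, ME for 6 <= value < 14,
#' SE for value >= 14.
#'
#' @param laa950_insp Percentage in \[0, 100\] (vectorized).
#' @return Factor with levels NE, ME, SE.
#' @export
emphysema_class <- function(laa950_insp) {
  if (any(!is.finite(laa950_insp)) || any(laa950_insp < 0 | laa950_insp > 100))
    abort_domain("%LAA-950insp must lie in [0, 100]")
  cls <- ifelse(laa950_insp < 6, "NE", ifelse(laa950_insp < 14, "ME", "SE"))
  factor(cls, levels = c("NE", "ME", "SE"))
}

#' Summarise a PRM label map
#'
#' Percentages of the four voxel classes over the mask, the raw %LAA metrics
#' recomputed from the attenuation grids, and the NE/ME/SE class. The four
#' class percentages partition to 100; %LAA-950insp equals pLDA + Other by
#' construction of the class rules.
#'
#' @param labels Label array from [prm_classify()].
#' @param study The [paired_ct_study()] the labels came from.
#' @return A one-row tibble: `pct_normal`, `pct_flda`, `pct_plda`,
#'   `pct_other`, `laa950_insp`, `laa856_exp`, `emphysema_class`.
#' @export
prm_summary <- function(labels, study) {
  if (!identical(dim(labels), dim(study$mask)))
    abort_malformed("labels and study shapes differ")
  inside <- labels[study$mask]
  n <- length(inside)
  pct <- 100 * tabulate(inside, nbins = 4L) / n
  laa950 <- laa_fraction(study$insp_hu, study$mask, -950)
  laa856 <- laa_fraction(study$exp_hu, study$mask, -856)
  tibble::tibble(
    pct_normal = pct[1L], pct_flda = pct[2L], pct_plda = pct[3L],
    pct_other = pct[4L],
    laa950_insp = laa950, laa856_exp = laa856,
    emphysema_class = emphysema_class(laa950)
  )
}

#' Read / write paired CT volumes as NIfTI
#'
#' @param insp_path,exp_path,mask_path NIfTI file paths (.nii or .nii.gz).
#' @return A [paired_ct_study()].
#' @export
read_paired_ct <- function(insp_path, exp_path, mask_path) {
  rd <- function(p) {
    arr <- as.array(RNifti::readNifti(p))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    arr
  }
  paired_ct_study(rd(insp_path), rd(exp_path), rd(mask_path) > 0)
}

#' @param labels Label array from [prm_classify()].
#' @param path Output NIfTI path; integer codes 0 outside mask, 1 Normal,
#'   2 fLDA, 3 pLDA, 4 Other.
#' @rdname read_paired_ct
#' @export
write_prm_labels <- function(labels, path) {
  out <- labels
  out[out == 5L] <- 0L
  attr(out, "levels") <- NULL
  RNifti::writeNifti(RNifti::asNifti(out, datatype = "int16"), path)
  invisible(path)
}

#' Generate a paired CT study matching target class fractions
#'
#' Builds voxel-aligned inspiratory/expiratory grids whose PRM composition
#' hits the requested fractions exactly up to one voxel's rounding. Voxel
#' counts per class are `round(target/100 * n_voxels)`; each voxel's HU pair
#' is drawn uniformly within its class-consistent range (with half-unit
#' margins away from the -950/-856 cut-offs, so the strict-inequality
#' boundary rule cannot flip a voxel). The mask covers the whole grid.
#'
#' @param dims Integer 3-vector grid shape.
#' @param targets Named list/vector with `laa950_insp`, `plda`, `flda`
#'   percentages; requires `plda <= laa950_insp`, all >= 0, and
#'   `laa950_insp - plda + plda + flda <= 100`.
#' @param seed Optional integer seed.
#' @return A [paired_ct_study()].
#' @export
generate_paired_ct <- function(dims = c(50L, 50L, 50L),
                               targets = list(laa950_insp = 10, plda = 8,
                                              flda = 25),
                               seed = NULL) {
  laa <- targets[["laa950_insp"]]
  plda <- targets[["plda"]]
  flda <- targets[["flda"]]
  if (any(c(laa, plda, flda) < 0) || plda > laa ||
      (laa - plda) + plda + flda > 100)
    abort_domain("inconsistent CT class targets")
  n <- prod(dims)
  n_plda <- round(plda / 100 * n)
  n_other <- max(round(laa / 100 * n) - n_plda, 0)
  n_flda <- round(flda / 100 * n)
  n_normal <- n - n_plda - n_other - n_flda
  if (n_normal < 0) abort_domain("targets exceed the grid capacity")
  with_seed_(seed, {
    idx <- sample.int(n)
    cls <- integer(n)
    take <- function(k) {
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    i_plda <- take(n_plda)
    i_other <- take(n_other)
    i_flda <- take(n_flda)
    i_norm <- idx
    insp <- numeric(n)
    expv <- numeric(n)
    low_i <- function(k) stats::runif(k, -1000, -950.5)
    high_i <- function(k) stats::runif(k, -949.5, -700)
    low_e <- function(k) stats::runif(k, -1000, -856.5)
    high_e <- function(k) stats::runif(k, -855.5, -600)
    insp[i_plda] <- low_i(n_plda);  expv[i_plda] <- low_e(n_plda)
    insp[i_other] <- low_i(n_other); expv[i_other] <- high_e(n_other)
    insp[i_flda] <- high_i(n_flda); expv[i_flda] <- low_e(n_flda)
    insp[i_norm] <- high_i(length(i_norm)); expv[i_norm] <- high_e(length(i_norm))
    paired_ct_study(array(insp, dim = dims), array(expv, dim = dims),
                    array(TRUE, dim = dims))
  })
}
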