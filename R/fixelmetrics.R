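# Fixel metrics: FC from warp Jacobians, logFC, FDC, and tract aggregation.

#' Fibre cross-section from a warp Jacobian
#'
#' The fibre cross-section (FC) of a fixel measures the change in
#' cross-sectional area of its fibre bundle under the subject-to-template
#' warp. For the local affine approximation `J` of the warp and fibre
#' direction `v`, the bundle's volume scales by `det(J)` and its length along
#' the fibre by `||J v||`, so the cross-sectional area scales by
#'
#'   FC = det(J) / ||J v||.
#'
#' The definition is antipodally symmetric: `FC(J, v) == FC(J, -v)`.
#'
#' @param jacobian 3x3 matrix, or a 3x3xN array for a whole fixel field.
#' @param direction Unit 3-vector, or an Nx3 matrix matching the array form.
#' @return FC scalar (or vector of length N), always > 0 for valid warps.
#' @examples
#' compute_fc(diag(3), c(0, 0, 1))          # identity warp: FC = 1
#' compute_fc(diag(c(2, 2, 1)), c(0, 0, 1)) # perpendicular plane doubled: 4
#' @export
compute_fc <- function(jacobian, direction) {
  if (is.matrix(jacobian)) {
    jacobian <- array(jacobian, dim = c(3, 3, 1))
    direction <- matrix(direction, nrow = 1)
  }
  direction <- matrix(direction, ncol = 3)
  n <- dim(jacobian)[3]
  if (nrow(direction) == 1 && n > 1)
    direction <- direction[rep(1, n), , drop = FALSE]
  nrm <- sqrt(rowSums(direction^2))
  if (any(nrm < 1e-12))
    stop_invalid("invalid fixel: zero direction vector")
  if (any(abs(nrm - 1) > 1e-6))
    stop_invalid("fixel direction must have unit norm")
  J <- jacobian
  dets <- J[1, 1, ] * (J[2, 2, ] * J[3, 3, ] - J[2, 3, ] * J[3, 2, ]) -
          J[1, 2, ] * (J[2, 1, ] * J[3, 3, ] - J[2, 3, ] * J[3, 1, ]) +
          J[1, 3, ] * (J[2, 1, ] * J[3, 2, ] - J[2, 2, ] * J[3, 1, ])
  if (any(dets <= 0))
    stop_invalid("invalid warp: Jacobian with non-positive determinant")
  Jv1 <- J[1, 1, ] * direction[, 1] + J[1, 2, ] * direction[, 2] +
         J[1, 3, ] * direction[, 3]
  Jv2 <- J[2, 1, ] * direction[, 1] + J[2, 2, ] * direction[, 2] +
         J[2, 3, ] * direction[, 3]
  Jv3 <- J[3, 1, ] * direction[, 1] + J[3, 2, ] * direction[, 2] +
         J[3, 3, ] * direction[, 3]
  fc <- dets / sqrt(Jv1^2 + Jv2^2 + Jv3^2)
  if (length(fc) == 1) fc[[1]] else fc
}

#' Fibre density and cross-section (FDC)
#'
#' Combined micro- and macrostructural metric, the product of fibre density
#' and fibre cross-section.
#'
#' @param fd Fibre density, >= 0 (vectorized).
#' @param fc Fibre cross-section, > 0 (vectorized).
#' @return `fd * fc`.
#' @export
compute_fdc <- function(fd, fc) {
  if (any(fd < 0, na.rm = TRUE)) stop_invalid("FD must be >= 0")
  if (any(fc <= 0, na.rm = TRUE)) stop_invalid("FC must be > 0")
  fd * fc
}

#' Per-fixel metrics for one subject record
#'
#' Computes FC from the stored warp Jacobians (unless a precomputed `fc` is
#' present), the natural-log FC used for statistics, and FDC.
#'
#' @param record One element of a cohort's `fixel_data` (fields `fd`,
#'   `jacobian`, optionally `fc`), or any list with those fields.
#' @param template The matching `fixel_template`.
#' @param use_precomputed_fc Use `record$fc` if present (default TRUE).
#' @return Data frame: `fixel_id`, `fd`, `fc`, `log_fc`, `fdc`.
#' @export
fixel_metrics <- function(record, template, use_precomputed_fc = TRUE) {
  fd <- record$fd
  if (any(fd < 0)) stop_invalid("FD must be >= 0")
  if (use_precomputed_fc && !is.null(record$fc)) {
    fc <- record$fc
  } else {
    dirs <- as.matrix(template$fixels[, c("dx", "dy", "dz")])
    fc <- compute_fc(record$jacobian, dirs)
  }
  data.frame(fixel_id = template$fixels$fixel_id, fd = fd, fc = fc,
             log_fc = log(fc), fdc = compute_fdc(fd, fc))
}

lesion_to_linear <- function(lesion_mask, dims) {
  if (is.null(lesion_mask)) return(integer(0))
  if (is.matrix(lesion_mask) || is.data.frame(lesion_mask))
    voxel_linear_id(as.matrix(lesion_mask), dims)
  else as.integer(lesion_mask)
}

#' Aggregate fixel metrics over atlas tracts
#'
#' Arithmetic mean of each metric over the fixels belonging to each tract,
#' optionally excluding fixels whose voxel falls inside a lesion mask
#' (lesions are voxel-level: a lesioned voxel removes all its fixels). A
#' tract left with no fixel after masking is omitted from the table and
#' reported through a warning (and in the `omitted` attribute).
#'
#' @param metrics Data frame from [fixel_metrics()] covering all template
#'   fixels.
#' @param template The `fixel_template`.
#' @param lesion_mask Optional voxel set: matrix of 0-based `(i,j,k)` triples
#'   or vector of linear voxel ids.
#' @param subject,timepoint Identifiers copied into the output rows.
#' @return Data frame: `subject`, `timepoint`, `tract`, `mean_fd`,
#'   `mean_logfc`, `mean_fdc`, `n_fixels_used`; attribute `omitted` lists
#'   tracts dropped by masking.
#' @export
aggregate_tracts <- function(metrics, template, lesion_mask = NULL,
                             subject = NA_character_, timepoint = NA_integer_) {
  fx <- template$fixels
  if (nrow(metrics) != nrow(fx) || !all(metrics$fixel_id == fx$fixel_id))
    stop_invalid("metrics must cover all template fixels, in template order")
  keep <- rep(TRUE, nrow(fx))
  les <- lesion_to_linear(lesion_mask, template$grid_dim)
  if (length(les)) {
    vox <- voxel_linear_id(fx[, c("i", "j", "k")], template$grid_dim)
    keep <- !(vox %in% les)
  }
  tracts <- template$tract_names
  out <- vector("list", length(tracts))
  omitted <- character(0)
  for (ti in seq_along(tracts)) {
    sel <- keep & fx$tract == tracts[ti]
    n_used <- sum(sel)
    if (n_used == 0) {
      omitted <- c(omitted, tracts[ti])
      next
    }
    out[[ti]] <- data.frame(
      subject = subject, timepoint = timepoint, tract = tracts[ti],
      mean_fd = mean(metrics$fd[sel]),
      mean_logfc = mean(metrics$log_fc[sel]),
      mean_fdc = mean(metrics$fdc[sel]),
      n_fixels_used = n_used, stringsAsFactors = FALSE)
  }
  if (length(omitted))
    warning(sprintf("tract(s) fully masked out and omitted: %s",
                    paste(omitted, collapse = ", ")), call. = FALSE)
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  attr(res, "omitted") <- omitted
  res
}

#' Tract metric table for a whole cohort
#'
#' Runs [fixel_metrics()] and [aggregate_tracts()] for every subject and
#' timepoint of a cohort, optionally masking each subject's own lesions.
#'
#' @param cohort A `fixel_cohort`.
#' @param mask_lesions Exclude each subject's lesioned voxels before
#'   averaging (default FALSE).
#' @return Data frame with one row per subject x timepoint x tract.
#' @export
tract_metric_table <- function(cohort, mask_lesions = FALSE) {
  rows <- lapply(cohort$fixel_data, function(rec) {
    m <- fixel_metrics(rec, cohort$template)
    mask <- if (mask_lesions) cohort$lesions[[rec$subject]] else NULL
    aggregate_tracts(m, cohort$template, lesion_mask = mask,
                     subject = rec$subject, timepoint = rec$timepoint)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
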