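# Synthetic cohort generation: fixel template, subjects, fixel metrics,
# cognition and clinical scores, with known ground-truth effects.

#' The 20 white-matter tract labels used throughout the package
#'
#' Mirrors the 20-tract white-matter partition of the JHU tractography atlas:
#' bilateral anterior thalamic radiation (ATR), cingulum (cingulate gyrus, CGC),
#' cingulum (hippocampal, CGH), corticospinal tract (CST), forceps major/minor,
#' inferior fronto-occipital fasciculus (IFOF), inferior longitudinal
#' fasciculus (ILF), superior longitudinal fasciculus (SLF), its temporal part
#' (SLFT) and the uncinate fasciculus (UNC).
#'
#' @return Character vector of 20 tract labels.
#' @export
tract_names <- function() {
  c("ATR_L", "ATR_R", "CGC_L", "CGC_R", "CGH_L", "CGH_R", "CST_L", "CST_R",
    "Fmajor", "Fminor", "IFOF_L", "IFOF_R", "ILF_L", "ILF_R", "SLF_L", "SLF_R",
    "SLFT_L", "SLFT_R", "UNC_L", "UNC_R")
}

#' The seven cognitive domains of the neuropsychological battery
#' @return Character vector of 7 domain names.
#' @export
cognitive_domains <- function() {
  c("verbal_memory", "verbal_fluency", "information_processing_speed",
    "visuospatial_memory", "attention", "working_memory",
    "executive_functioning")
}

default_cognition_loading <- function() {
  tr <- tract_names()
  dm <- cognitive_domains()
  L <- matrix(0, nrow = length(dm), ncol = length(tr),
              dimnames = list(dm, tr))
  # Each domain draws on a small set of association pathways; weights chosen
  # once so that default group deficits produce impairment rates of the order
  # seen in mixed MS cohorts (see methods vignette).
  picks <- list(
    verbal_memory                = c("CGH_L", "CGH_R", "UNC_L"),
    verbal_fluency               = c("UNC_R", "IFOF_L", "ILF_L"),
    information_processing_speed = c("SLF_L", "SLF_R", "Fmajor"),
    visuospatial_memory          = c("ILF_R", "IFOF_R", "Fmajor"),
    attention                    = c("CGC_L", "CGC_R", "SLF_R"),
    working_memory               = c("SLFT_L", "SLFT_R", "Fminor"),
    executive_functioning        = c("CGC_L", "SLF_L", "Fminor")
  )
  for (d in dm) L[d, picks[[d]]] <- 0.35
  L
}

per_group <- function(hc, ms) c(HC = hc, RRMS = ms, SPMS = ms, PPMS = ms)

default_tract_effects <- function() {
  tr <- tract_names()
  fd <- cbind(RRMS = rep(0.05, 20), SPMS = rep(0.10, 20), PPMS = rep(0.05, 20))
  fc <- cbind(RRMS = rep(0.02, 20), SPMS = rep(0.06, 20), PPMS = rep(0.02, 20))
  rownames(fd) <- rownames(fc) <- tr
  list(fd = fd, fc = fc)
}

default_slope_effects <- function() {
  tr <- tract_names()
  fd <- cbind(HC = rep(0, 20), RRMS = rep(-0.002, 20),
              SPMS = rep(-0.008, 20), PPMS = rep(-0.006, 20))
  fc <- cbind(HC = rep(0, 20), RRMS = rep(-0.001, 20),
              SPMS = rep(-0.004, 20), PPMS = rep(-0.003, 20))
  rownames(fd) <- rownames(fc) <- tr
  list(fd = fd, fc = fc)
}

#' Simulation configuration for synthetic cohorts
#'
#' Builds a fully populated configuration, starting from defaults calibrated
#' to the cohort structure of a longitudinal multiple sclerosis study:
#' 95 healthy controls (HC) and 327 patients (239 relapsing-remitting RRMS,
#' 52 secondary progressive SPMS, 36 primary progressive PPMS), with 233/327
#' patients and 61/95 controls retained at a follow-up visit roughly five
#' years later (patients 4.81 +/- 0.85 y, controls 5.43 +/- 1.07 y).
#'
#' Tract-level healthy-control means of fibre density (FD ~ 0.5) and fibre
#' cross-section (FC = 1 by construction) are order-of-magnitude choices, as
#' no per-tract reference values are published; see the methods vignette.
#'
#' @param ... Named overrides of any default. Nested lists are merged
#'   element-wise (`modifyList` semantics).
#' @return Object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 7, group_sizes = c(HC = 10, RRMS = 10, SPMS = 5, PPMS = 5))
#' cfg$group_sizes
#' @export
simulation_config <- function(...) {
  tr <- tract_names()
  defaults <- list(
    group_sizes = c(HC = 95, RRMS = 239, SPMS = 52, PPMS = 36),
    followup_fraction = c(HC = 61 / 95, RRMS = 233 / 327,
                          SPMS = 233 / 327, PPMS = 233 / 327),
    interval_years = list(HC = c(mean = 5.43, sd = 1.07),
                          RRMS = c(mean = 4.81, sd = 0.85),
                          SPMS = c(mean = 4.81, sd = 0.85),
                          PPMS = c(mean = 4.81, sd = 0.85)),
    age = list(HC = c(mean = 45.70, sd = 10.35),
               RRMS = c(mean = 48.34, sd = 10.95),
               SPMS = c(mean = 48.34, sd = 10.95),
               PPMS = c(mean = 48.34, sd = 10.95)),
    sex_female = per_group(55 / 95, 221 / 327),
    education_high = per_group(56 / 95, 149 / 327),
    head_scale = c(mean = 1.0, sd = 0.04),
    symptom_duration = c(mean = 14.67, sd = 8.46),
    fd_mean = stats::setNames(rep(0.5, 20), tr),
    fc_mean = 1.0,
    tract_effects = default_tract_effects(),
    slope_effects = default_slope_effects(),
    noise = c(between_sd = 0.06, within_sd = 0.015, fixel_sd = 0.02),
    lesion = list(
      expected_voxels = c(RRMS = 25, SPMS = 45, PPMS = 35),
      tract_weights = stats::setNames(rep(1, 20), tr),
      attenuation = 0.5,
      load_mean = c(RRMS = 12, SPMS = 22, PPMS = 16),
      load_sd = c(RRMS = 10, SPMS = 15, PPMS = 12)
    ),
    cognition = list(
      loading = default_cognition_loading(),
      domain_sd = 0.9,
      age_coef = -0.03,
      sex_coef = -0.15,
      edu_coef = 0.55,
      intercept = 0
    ),
    edss = list(base = c(RRMS = 2.5, SPMS = 5.5, PPMS = 4.5),
                damage_coef = 0.6, sd = 0.9,
                progression = c(RRMS = 0.3, SPMS = 0.9, PPMS = 0.7)),
    volumes = list(
      NBV   = list(HC = c(1517.23, 66.67), MS = c(1451.12, 78.19)),
      NWMV  = list(HC = c(697.73, 30.82),  MS = c(668.34, 35.49)),
      NCGMV = list(HC = c(780.39, 51.65),  MS = c(748.07, 53.74)),
      NDGMV = list(HC = c(62.95, 3.73),    MS = c(56.00, 6.84))
    ),
    treatment = c(IFb = 72, GA = 16, NTZ = 22, other = 6, none = 211) / 327,
    template = list(grid_dim = c(20L, 20L, 20L), voxel_size = 1.25,
                    streamlines_per_tract = 50L),
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop_invalid("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  cfg <- validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (any(cfg$group_sizes < 0) || any(cfg$group_sizes != round(cfg$group_sizes)))
    stop_invalid("group_sizes must be non-negative integers")
  if (any(cfg$followup_fraction < 0 | cfg$followup_fraction > 1))
    stop_invalid("followup_fraction must lie in [0, 1]")
  for (m in c("fd", "fc")) {
    d <- cfg$tract_effects[[m]]
    if (any(d < 0 | d >= 1))
      stop_invalid("fractional %s deficits must lie in [0, 1)", toupper(m))
  }
  if (any(cfg$noise < 0)) stop_invalid("noise SDs must be >= 0")
  if (any(cfg$fd_mean <= 0) || cfg$fc_mean <= 0)
    stop_invalid("tract FD/FC means must be positive")
  if (cfg$lesion$attenuation < 0 || cfg$lesion$attenuation > 1)
    stop_invalid("lesion attenuation must lie in [0, 1]")
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                         collapse = " "), "\n")
  cat("  grid:", paste(x$template$grid_dim, collapse = "x"),
      " voxel", x$template$voxel_size, "mm\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Template generation

#' Generate a synthetic fixel template
#'
#' Lays out the 20 atlas tracts as connected axis-aligned voxel paths on a
#' regular grid, with one fixel per voxel along each path. Paths of different
#' orientation deliberately intersect, producing crossing-fibre voxels with
#' two or three fixels (never more); every fixel keeps its own tract label.
#' Each tract carries a set of streamlines (contiguous sub-paths of its fixel
#' sequence) used to build fixel-to-fixel connectivity.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to a substream derived from
#'   `config$seed`.
#' @return Object of class `fixel_template` with elements `grid_dim`,
#'   `voxel_size`, `fixels` (data frame: `fixel_id`, `i`,`j`,`k`,
#'   `dx`,`dy`,`dz`, `tract`; 0-based ids and voxel indices) and
#'   `streamlines` (list of 0-based fixel-id vectors).
#' @export
generate_template <- function(config = simulation_config(), seed = NULL) {
  seed <- seed %||% substream_seed(config$seed, "template")
  dims <- as.integer(config$template$grid_dim)
  if (length(dims) != 3 || any(dims < 10))
    stop_invalid(
      "grid %s too small: need at least 10 voxels per axis to embed 20 tracts",
      paste(dims, collapse = "x"))
  tr <- tract_names()
  with_seed(seed, {
    x_tr <- tr[1:10]; y_tr <- tr[11:18]; z_tr <- tr[19:20]
    y_lanes <- floor(seq(0, dims[2] - 1, length.out = 10))
    x_lanes <- floor(seq(0, dims[1] - 1, length.out = 8))
    z_levels <- floor(seq(1, dims[3] - 2, length.out = 3))
    z_of_x <- sample(rep(z_levels, length.out = 10))
    z_of_y <- sample(rep(z_levels, length.out = 8))

    paths <- vector("list", 20); names(paths) <- tr
    dirs <- matrix(0, 20, 3, dimnames = list(tr, NULL))
    for (i in 1:10) {
      paths[[x_tr[i]]] <- cbind(0:(dims[1] - 1), y_lanes[i], z_of_x[i])
      dirs[x_tr[i], ] <- c(1, 0, 0)
    }
    for (j in 1:8) {
      paths[[y_tr[j]]] <- cbind(x_lanes[j], 0:(dims[2] - 1), z_of_y[j])
      dirs[y_tr[j], ] <- c(0, 1, 0)
    }
    # Vertical tracts placed on (x, y) lanes of an intersecting x/y pair so
    # at least one voxel holds three crossing fixels.
    match_xy <- which(outer(z_of_x, z_of_y, "=="), arr.ind = TRUE)
    if (nrow(match_xy) < 2)
      stop_invalid("template layout failed to produce crossing lanes")
    pick <- match_xy[sample(nrow(match_xy), 2), , drop = FALSE]
    for (k in 1:2) {
      a <- pick[k, 1]; b <- pick[k, 2]
      paths[[z_tr[k]]] <- cbind(x_lanes[b], y_lanes[a], 0:(dims[3] - 1))
      dirs[z_tr[k], ] <- c(0, 0, 1)
    }

    fx <- do.call(rbind, lapply(tr, function(t) {
      p <- unname(paths[[t]])
      v <- unname(dirs[t, ])
      data.frame(i = p[, 1], j = p[, 2], k = p[, 3],
                 dx = v[1], dy = v[2], dz = v[3],
                 tract = t, stringsAsFactors = FALSE)
    }))
    fx <- cbind(fixel_id = seq_len(nrow(fx)) - 1L, fx)

    counts <- table(voxel_linear_id(fx[, c("i", "j", "k")], dims))
    if (any(counts > 3))
      stop_invalid("template layout produced a voxel with >3 fixels")

    n_str <- config$template$streamlines_per_tract
    first_id <- c(0L, cumsum(vapply(paths, nrow, 0L)))[seq_along(tr)]
    names(first_id) <- tr
    streamlines <- list()
    for (t in tr) {
      L <- nrow(paths[[t]]); off <- max(0L, floor(L * 0.2))
      ids <- first_id[[t]] + 0:(L - 1L)
      for (s in seq_len(n_str)) {
        a <- sample.int(off + 1L, 1L) - 1L
        b <- L - sample.int(off + 1L, 1L)
        streamlines[[length(streamlines) + 1L]] <- as.integer(ids[(a + 1):b])
      }
    }

    structure(list(grid_dim = dims, voxel_size = config$template$voxel_size,
                   fixels = fx, streamlines = streamlines,
                   tract_names = tr),
              class = "fixel_template")
  })
}

#' Validate fixel-template invariants
#'
#' Checks: at most 3 fixels per voxel, unit-norm directions (1e-9), all
#' streamline fixel ids exist, and every tract label owns at least one fixel.
#'
#' @param template A `fixel_template`.
#' @return The template, invisibly; signals a validation error otherwise.
#' @export
validate_template <- function(template) {
  fx <- template$fixels
  counts <- table(voxel_linear_id(fx[, c("i", "j", "k")], template$grid_dim))
  if (any(counts > 3)) stop_invalid("voxel with more than 3 fixels")
  norms <- sqrt(fx$dx^2 + fx$dy^2 + fx$dz^2)
  if (any(abs(norms - 1) > 1e-9))
    stop_invalid("fixel direction with non-unit norm")
  ids <- fx$fixel_id
  allref <- unlist(template$streamlines, use.names = FALSE)
  if (length(allref) && (min(allref) < 0 || max(allref) > max(ids) ||
                         !all(allref %in% ids)))
    stop_invalid("streamline references a non-existent fixel")
  missing <- setdiff(tract_names(), unique(fx$tract))
  if (length(missing))
    stop_invalid("tract label(s) with no fixels: %s",
                 paste(missing, collapse = ", "))
  invisible(template)
}

#' @export
print.fixel_template <- function(x, ...) {
  cat("<fixel_template>", nrow(x$fixels), "fixels,",
      length(x$streamlines), "streamlines,",
      paste(x$grid_dim, collapse = "x"), "grid\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cohort generation

ms_groups <- function() c("RRMS", "SPMS", "PPMS")

round_half <- function(x) round(x * 2) / 2

# Jacobian field for one record: J_f = v v' + s cos(th) (I - v v')
#                                      + s sin(th) (w u' - u w'),
# an affine map that fixes the fibre axis (J v = v) and scales the
# perpendicular plane by s (with an in-plane rotation th), so that
# det(J)/||J v|| = s^2 exactly. Setting s = sqrt(FC) realises any intended
# FC field in closed form.
jacobian_field <- function(basis, s, theta) {
  a <- rep(s * cos(theta), each = 9L)
  b <- rep(s * sin(theta), each = 9L)
  basis$P0 + basis$P1 * a + basis$P2 * b
}

fixel_bases <- function(template) {
  fx <- template$fixels
  n <- nrow(fx)
  P0 <- P1 <- P2 <- array(0, dim = c(3, 3, n))
  V <- as.matrix(fx[, c("dx", "dy", "dz")])
  for (f in seq_len(n)) {
    v <- V[f, ]
    bb <- perp_basis(v)
    P0[, , f] <- tcrossprod(v)
    P1[, , f] <- diag(3) - tcrossprod(v)
    P2[, , f] <- tcrossprod(bb$w, bb$u) - tcrossprod(bb$u, bb$w)
  }
  list(P0 = P0, P1 = P1, P2 = P2)
}

#' Generate a complete synthetic cohort
#'
#' Draws a template and a two-timepoint cohort under the configured
#' ground-truth effects: healthy-control tract FD around per-tract means,
#' multiplicative phenotype deficits `(1 - deficit)`, annual fractional
#' slopes applied over each subject's follow-up interval, log-normal
#' between-subject and measurement noise, warp Jacobians realising the
#' intended FC field exactly, lesion voxel sets with tract-weighted
#' placement, cognition driven by standardized tract FDC through a loading
#' matrix, and EDSS/volumes/treatment covariates.
#'
#' Follow-up retention is deterministic in count: each group keeps
#' `round(followup_fraction * n)` subjects (which subjects is seeded).
#'
#' @param config A [simulation_config()].
#' @return Object of class `fixel_cohort`: `template`, `subjects` (one row
#'   per subject x timepoint), `fixel_data` (per record: `fd`, `fc`,
#'   `jacobian`), `cognition` (raw domain scores), `lesions` (per-subject
#'   0-based voxel triples) and `ground_truth`.
#' @examples
#' cfg <- simulation_config(seed = 42,
#'   group_sizes = c(HC = 12, RRMS = 12, SPMS = 6, PPMS = 6),
#'   template = list(grid_dim = c(12L, 12L, 12L), streamlines_per_tract = 10L))
#' coh <- generate_cohort(cfg)
#' table(coh$subjects$group, coh$subjects$timepoint)
#' @export
generate_cohort <- function(config = simulation_config()) {
  config <- validate_config(config)
  seed <- config$seed
  template <- generate_template(config, seed = substream_seed(seed, "template"))
  tr <- template$tract_names
  n_tr <- length(tr)
  fx <- template$fixels
  tract_idx <- match(fx$tract, tr)
  nfix <- nrow(fx)
  groups <- names(config$group_sizes)

  # -- subjects & covariates ------------------------------------------------
  subj <- with_seed(substream_seed(seed, "subjects"), {
    rows <- lapply(groups, function(g) {
      n <- config$group_sizes[[g]]
      if (n == 0) return(NULL)
      data.frame(
        subject = sprintf("%s%03d", g, seq_len(n)),
        group = g,
        age = stats::rnorm(n, config$age[[g]]["mean"], config$age[[g]]["sd"]),
        sex = stats::rbinom(n, 1, 1 - config$sex_female[[g]]),  # 1 = male
        education_high = stats::rbinom(n, 1, config$education_high[[g]]),
        head_scale = stats::rnorm(n, config$head_scale["mean"],
                                  config$head_scale["sd"]),
        interval_years = pmax(0.5, stats::rnorm(
          n, config$interval_years[[g]]["mean"],
          config$interval_years[[g]]["sd"])),
        symptom_duration = if (g == "HC") NA_real_ else
          pmax(0.5, stats::rnorm(n, config$symptom_duration["mean"],
                                 config$symptom_duration["sd"])),
        treatment = if (g == "HC") "none" else
          sample(names(config$treatment), n, replace = TRUE,
                 prob = config$treatment),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  subj$age <- pmax(18, subj$age)
  ns <- nrow(subj)

  vols <- with_seed(substream_seed(seed, "volumes"), {
    out <- matrix(NA_real_, ns, 4,
                  dimnames = list(NULL, c("NBV", "NWMV", "NCGMV", "NDGMV")))
    for (v in colnames(out)) {
      par <- config$volumes[[v]]
      is_hc <- subj$group == "HC"
      out[is_hc, v] <- stats::rnorm(sum(is_hc), par$HC[1], par$HC[2])
      out[!is_hc, v] <- stats::rnorm(sum(!is_hc), par$MS[1], par$MS[2])
    }
    out
  })

  dropout <- with_seed(substream_seed(seed, "dropout"), {
    keep <- character(0)
    for (g in groups) {
      ids <- subj$subject[subj$group == g]
      n_keep <- round(config$followup_fraction[[g]] * length(ids))
      if (n_keep > 0) keep <- c(keep, sample(ids, n_keep))
    }
    keep
  })

  # -- intended tract-level FD / FC  ---------------------------------------
  deficit_fd <- matrix(0, ns, n_tr)
  deficit_fc <- matrix(0, ns, n_tr)
  slope_fd <- matrix(0, ns, n_tr)
  slope_fc <- matrix(0, ns, n_tr)
  for (g in setdiff(groups, "HC")) {
    sel <- subj$group == g
    deficit_fd[sel, ] <- matrix(config$tract_effects$fd[tr, g], sum(sel),
                                n_tr, byrow = TRUE)
    deficit_fc[sel, ] <- matrix(config$tract_effects$fc[tr, g], sum(sel),
                                n_tr, byrow = TRUE)
  }
  for (g in groups) {
    sel <- subj$group == g
    slope_fd[sel, ] <- matrix(config$slope_effects$fd[tr, g], sum(sel),
                              n_tr, byrow = TRUE)
    slope_fc[sel, ] <- matrix(config$slope_effects$fc[tr, g], sum(sel),
                              n_tr, byrow = TRUE)
  }

  nz <- with_seed(substream_seed(seed, "noise"), {
    list(
      eta_fd = stats::rnorm(ns, 0, config$noise["between_sd"]),
      eta_fc = stats::rnorm(ns, 0, config$noise["between_sd"]),
      eps_fd1 = matrix(stats::rnorm(ns * n_tr, 0, config$noise["within_sd"]),
                       ns, n_tr),
      eps_fd2 = matrix(stats::rnorm(ns * n_tr, 0, config$noise["within_sd"]),
                       ns, n_tr),
      eps_fc1 = matrix(stats::rnorm(ns * n_tr, 0, config$noise["within_sd"]),
                       ns, n_tr),
      eps_fc2 = matrix(stats::rnorm(ns * n_tr, 0, config$noise["within_sd"]),
                       ns, n_tr)
    )
  })

  fd_base <- matrix(config$fd_mean[tr], ns, n_tr, byrow = TRUE)
  growth_fd <- 1 + slope_fd * subj$interval_years
  growth_fc <- 1 + slope_fc * subj$interval_years
  if (any((1 - deficit_fc) * growth_fc <= 0) || any(config$fc_mean <= 0))
    stop_invalid("configuration implies a non-positive intended FC")
  if (any((1 - deficit_fd) * growth_fd <= 0))
    stop_invalid("configuration implies a non-positive intended FD")

  tract_fd1 <- fd_base * (1 - deficit_fd) * exp(nz$eta_fd + nz$eps_fd1)
  tract_fd2 <- fd_base * (1 - deficit_fd) * growth_fd *
    exp(nz$eta_fd + nz$eps_fd2)
  tract_fc1 <- config$fc_mean * (1 - deficit_fc) * exp(nz$eta_fc + nz$eps_fc1)
  tract_fc2 <- config$fc_mean * (1 - deficit_fc) * growth_fc *
    exp(nz$eta_fc + nz$eps_fc2)
  dimnames(tract_fd1) <- dimnames(tract_fd2) <- dimnames(tract_fc1) <-
    dimnames(tract_fc2) <- list(subj$subject, tr)

  # -- lesions --------------------------------------------------------------
  vox_key <- voxel_linear_id(fx[, c("i", "j", "k")], template$grid_dim)
  path_vox <- unique(vox_key)
  vox_weight <- vapply(path_vox, function(v) {
    max(config$lesion$tract_weights[fx$tract[vox_key == v]])
  }, 0)
  lesions <- with_seed(substream_seed(seed, "lesions"), {
    out <- list()
    for (s in seq_len(ns)) {
      g <- subj$group[s]
      if (g == "HC") next
      n_vox <- stats::rpois(1, config$lesion$expected_voxels[[g]])
      n_vox <- min(n_vox, length(path_vox))
      if (n_vox == 0) next
      sel <- sample(seq_along(path_vox), n_vox, prob = vox_weight)
      out[[subj$subject[s]]] <- path_vox[sel]
    }
    out
  })
  lesion_load <- with_seed(substream_seed(seed, "lesionload"), {
    ll <- rep(NA_real_, ns)
    for (g in ms_groups()) {
      sel <- subj$group == g
      ll[sel] <- pmax(0.1, stats::rnorm(sum(sel), config$lesion$load_mean[[g]],
                                        config$lesion$load_sd[[g]]))
    }
    ll
  })

  # -- fixel-level data -----------------------------------------------------
  basis <- fixel_bases(template)
  atten <- config$lesion$attenuation
  d_fix_fd <- deficit_fd[, tract_idx, drop = FALSE]
  fixel_data <- list()
  rec_subject <- character(0); rec_tp <- integer(0)
  fixseed <- substream_seed(seed, "fixel")
  for (tp in 1:2) {
    keep <- if (tp == 1) subj$subject else intersect(subj$subject, dropout)
    tfd <- if (tp == 1) tract_fd1 else tract_fd2
    tfc <- if (tp == 1) tract_fc1 else tract_fc2
    rows <- match(keep, subj$subject)
    jit <- with_seed(substream_seed(fixseed, paste0("tp", tp)), {
      list(fd = matrix(stats::rnorm(length(rows) * nfix, 0,
                                    config$noise["fixel_sd"]),
                       length(rows), nfix),
           fc = matrix(stats::rnorm(length(rows) * nfix, 0,
                                    config$noise["fixel_sd"]),
                       length(rows), nfix),
           theta = matrix(stats::rnorm(length(rows) * nfix, 0, 0.1),
                          length(rows), nfix))
    })
    for (r in seq_along(rows)) {
      s <- rows[r]
      fd_f <- unname(tfd[s, tract_idx]) * exp(jit$fd[r, ])
      fc_f <- unname(tfc[s, tract_idx]) * exp(jit$fc[r, ])
      les <- lesions[[subj$subject[s]]]
      if (!is.null(les)) {
        in_les <- vox_key %in% les
        d <- d_fix_fd[s, in_les]
        # inside lesions the apparent diffuse FD deficit is attenuated
        fd_f[in_les] <- fd_f[in_les] * (1 - d * (1 - atten)) / (1 - d)
      }
      J <- jacobian_field(basis, sqrt(fc_f), jit$theta[r, ])
      key <- paste0(subj$subject[s], "|", tp)
      fixel_data[[key]] <- list(subject = subj$subject[s], timepoint = tp,
                                fd = fd_f, fc = fc_f, jacobian = J)
      rec_subject <- c(rec_subject, subj$subject[s])
      rec_tp <- c(rec_tp, tp)
    }
  }

  # -- cognition ------------------------------------------------------------
  # Standardize intended tract FDC against the healthy controls of the same
  # timepoint; domain scores are an affine function of these z values plus
  # normative covariate effects and noise.
  tract_fdc1 <- tract_fd1 * tract_fc1
  tract_fdc2 <- tract_fd2 * tract_fc2
  hc1 <- subj$group == "HC"
  hc2 <- hc1 & subj$subject %in% dropout
  std <- function(M, ref) {
    mu <- colMeans(M[ref, , drop = FALSE])
    sd <- apply(M[ref, , drop = FALSE], 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-12] <- 1
    sweep(sweep(M, 2, mu), 2, sd, "/")
  }
  z1 <- std(tract_fdc1, hc1)
  z2 <- std(tract_fdc2, if (any(hc2)) hc2 else hc1)

  cg <- config$cognition
  L <- cg$loading[, tr, drop = FALSE]
  n_dom <- nrow(L)
  cognition <- with_seed(substream_seed(seed, "cognition"), {
    out <- list()
    for (tp in 1:2) {
      keep <- if (tp == 1) subj$subject else intersect(subj$subject, dropout)
      rows <- match(keep, subj$subject)
      zz <- if (tp == 1) z1 else z2
      age_tp <- subj$age[rows] + if (tp == 2) subj$interval_years[rows] else 0
      base <- cg$intercept + cg$age_coef * age_tp + cg$sex_coef * subj$sex[rows] +
        cg$edu_coef * subj$education_high[rows]
      damage <- zz[rows, , drop = FALSE] %*% t(L)   # subjects x domains
      noise <- matrix(stats::rnorm(length(rows) * n_dom, 0, cg$domain_sd),
                      length(rows), n_dom)
      sc <- base + damage + noise
      colnames(sc) <- cognitive_domains()
      out[[tp]] <- data.frame(subject = keep, timepoint = tp, sc,
                              stringsAsFactors = FALSE, row.names = NULL)
    }
    do.call(rbind, out)
  })

  # -- EDSS -----------------------------------------------------------------
  edss <- with_seed(substream_seed(seed, "edss"), {
    e1 <- rep(NA_real_, ns); e2 <- rep(NA_real_, ns)
    dmg <- -rowMeans(z1)
    for (g in ms_groups()) {
      sel <- which(subj$group == g)
      raw <- config$edss$base[[g]] + config$edss$damage_coef * dmg[sel] +
        stats::rnorm(length(sel), 0, config$edss$sd)
      e1[sel] <- pmin(9, pmax(0, round_half(raw)))
      raw2 <- e1[sel] + config$edss$progression[[g]] +
        stats::rnorm(length(sel), 0, 0.4)
      e2[sel] <- pmin(9, pmax(0, round_half(raw2)))
    }
    list(e1 = e1, e2 = e2)
  })

  # -- assemble subject table (one row per subject x timepoint) -------------
  base_df <- data.frame(subj, vols, lesion_load = lesion_load,
                        stringsAsFactors = FALSE, row.names = NULL)
  tp1 <- base_df
  tp1$timepoint <- 1L; tp1$time_years <- 0; tp1$edss <- edss$e1
  tp2 <- base_df[base_df$subject %in% dropout, ]
  tp2$timepoint <- 2L
  tp2$time_years <- tp2$interval_years
  tp2$age <- tp2$age + tp2$interval_years
  tp2$edss <- edss$e2[match(tp2$subject, subj$subject)]
  subjects <- rbind(tp1, tp2)
  rownames(subjects) <- NULL

  lesions_ijk <- lapply(lesions, function(v) {
    k <- v %/% (template$grid_dim[1] * template$grid_dim[2])
    rem <- v %% (template$grid_dim[1] * template$grid_dim[2])
    cbind(i = rem %% template$grid_dim[1],
          j = rem %/% template$grid_dim[1], k = k)
  })

  ground_truth <- list(
    config = config,
    tract_fd = list(tract_fd1, tract_fd2),
    tract_fc = list(tract_fc1, tract_fc2),
    tract_fdc_z = list(z1, z2),
    retained = dropout
  )

  structure(list(template = template, subjects = subjects,
                 fixel_data = fixel_data, cognition = cognition,
                 lesions = lesions_ijk, ground_truth = ground_truth),
            class = "fixel_cohort")
}

#' @export
print.fixel_cohort <- function(x, ...) {
  s <- x$subjects
  cat("<fixel_cohort>\n")
  print(table(group = s$group, timepoint = s$timepoint))
  invisible(x)
}

#' Cohort descriptives
#'
#' Counts, retention and composition percentages of a cohort (or of a bare
#' configuration, in which case only design-determined quantities are
#' reported). Percentages are computed from the counts, e.g. patient
#' follow-up retention = 100 * retained patients / baseline patients.
#'
#' @param cohort A `fixel_cohort`.
#' @return A list with `n_baseline` per group, `n_followup` per group, the
#'   derived percentages, and (if cognition has been classified upstream)
#'   nothing else -- cognitive class frequencies come from
#'   [cognitive_profiles()].
#' @export
cohort_summary <- function(cohort) {
  s <- cohort$subjects
  b <- s[s$timepoint == 1L, ]
  f <- s[s$timepoint == 2L, ]
  n_b <- table(factor(b$group, levels = unique(b$group)))
  n_f <- table(factor(f$group, levels = unique(b$group)))
  ms_b <- sum(n_b[names(n_b) != "HC"])
  ms_f <- sum(n_f[names(n_f) != "HC"])
  list(
    n_baseline = c(as.list(n_b), total_MS = ms_b),
    n_followup = c(as.list(n_f), total_MS = ms_f),
    pct_followup_MS = 100 * ms_f / ms_b,
    pct_followup_HC = if ("HC" %in% names(n_b) && n_b[["HC"]] > 0)
      100 * n_f[["HC"]] / n_b[["HC"]] else NA_real_,
    mean_age = tapply(b$age, b$group, mean),
    pct_female = 100 * tapply(1 - b$sex, b$group, mean),
    mean_interval = tapply(f$interval_years, f$group, mean)
  )
}
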