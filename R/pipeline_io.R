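# Pipeline IO: plain TSV / JSON-lines formats, configuration, run manifests
# and the command-line entry point.
#
# Conventions honored by every module: 0-based fixel ids and voxel indices,
# tab-separated UTF-8 with '.' decimal, fibre directions antipodally
# equivalent.

valid_groups <- function() c("HC", "RRMS", "SPMS", "PPMS")

#' Write / read the cohort subject table
#'
#' Tab-separated, one row per subject x timepoint, mirroring the usual
#' cohort descriptive variables (group, age, sex, education, head-size
#' scale, EDSS, normalized volumes NBV/NWMV/NCGMV/NDGMV, lesion load).
#' Reading validates: known group labels, non-negative volumes, unique
#' (subject, timepoint) pairs. EDSS may be missing for healthy controls
#' (disability is assessed in patients only).
#'
#' @param subjects Cohort subject data frame.
#' @param path File path.
#' @return `read_cohort_table` returns the validated data frame;
#'   `write_cohort_table` returns `path` invisibly.
#' @export
write_cohort_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  req <- c("subject", "timepoint", "group", "age", "sex")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop_invalid("cohort table missing column(s): %s",
                 paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$group), valid_groups())
  if (length(bad))
    stop_invalid("unknown group label(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(valid_groups(), collapse = ", "))
  for (v in intersect(c("NBV", "NWMV", "NCGMV", "NDGMV"), names(d)))
    if (any(d[[v]] < 0, na.rm = TRUE))
      stop_invalid("negative volume in column %s", v)
  key <- paste0(d$subject, "|", d$timepoint)
  if (anyDuplicated(key))
    stop_invalid("duplicate (subject, timepoint) row(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = ", "))
  d
}

#' Write / read a fixel template
#'
#' Fixels as TSV (`fixel_id`, `i`, `j`, `k`, `dx`, `dy`, `dz`, `tract`;
#' 0-based) and streamlines as JSON lines (one array of fixel ids per
#' line). Reading validates the template invariants: unit directions,
#' known tract labels, existing streamline references.
#'
#' @param template A `fixel_template`.
#' @param fixel_path Path of the fixel TSV.
#' @param streamline_path Path of the streamline JSON-lines file.
#' @param grid_dim,voxel_size Grid metadata for `read_fixel_template`
#'   (grid defaults to the bounding box of the fixels).
#' @return `read_fixel_template` returns a validated `fixel_template`.
#' @export
write_fixel_template <- function(template, fixel_path, streamline_path) {
  utils::write.table(template$fixels, fixel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(streamline_path, "w")
  on.exit(close(con))
  for (s in template$streamlines)
    writeLines(jsonlite::toJSON(s), con)
  invisible(fixel_path)
}

#' @rdname write_fixel_template
#' @export
read_fixel_template <- function(fixel_path, streamline_path,
                                grid_dim = NULL, voxel_size = 1.25) {
  fx <- utils::read.table(fixel_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("fixel_id", "i", "j", "k", "dx", "dy", "dz", "tract")
  miss <- setdiff(req, names(fx))
  if (length(miss))
    stop_invalid("fixel table missing column(s): %s",
                 paste(miss, collapse = ", "))
  norms <- sqrt(fx$dx^2 + fx$dy^2 + fx$dz^2)
  if (any(abs(norms - 1) > 1e-9))
    stop_invalid("non-unit fixel direction at fixel_id %s",
                 paste(fx$fixel_id[abs(norms - 1) > 1e-9], collapse = ", "))
  bad <- setdiff(unique(fx$tract), tract_names())
  if (length(bad))
    stop_invalid("unknown tract label(s) %s; valid labels: %s",
                 paste(bad, collapse = ", "),
                 paste(tract_names(), collapse = ", "))
  streamlines <- lapply(readLines(streamline_path), function(l)
    as.integer(jsonlite::fromJSON(l)))
  if (is.null(grid_dim))
    grid_dim <- c(max(fx$i), max(fx$j), max(fx$k)) + 1L
  tpl <- structure(list(grid_dim = as.integer(grid_dim),
                        voxel_size = voxel_size, fixels = fx,
                        streamlines = streamlines,
                        tract_names = intersect(tract_names(),
                                                unique(fx$tract))),
                   class = "fixel_template")
  validate_template(tpl)
  tpl
}

#' Write / read a tract metric table
#' @param table Tract metric table data frame.
#' @param path File path.
#' @export
write_tract_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tract_table
#' @export
read_tract_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read per-fixel scalar values from a plain-text fixel directory
#'
#' Adapter for outputs laid out in the fixel-directory convention of common
#' fixel-based analysis software, transcribed to plain text: an `index.tsv`
#' mapping voxels to fixel runs (`i`, `j`, `k`, `first_fixel`, `count`,
#' 0-based) and one or more per-fixel value files (single `value` column,
#' one row per fixel in index order).
#'
#' @param dir Directory containing `index.tsv`.
#' @param value_file File name of the per-fixel scalar file.
#' @return Data frame `fixel_id`, `i`, `j`, `k`, `value`.
#' @export
read_fixel_directory <- function(dir, value_file = "fd.tsv") {
  idx <- utils::read.table(file.path(dir, "index.tsv"), sep = "\t",
                           header = TRUE)
  val <- utils::read.table(file.path(dir, value_file), sep = "\t",
                           header = TRUE)
  n <- sum(idx$count)
  if (nrow(val) != n)
    stop_invalid("value file has %d rows but index declares %d fixels",
                 nrow(val), n)
  ord <- order(idx$first_fixel)
  idx <- idx[ord, ]
  data.frame(fixel_id = 0:(n - 1),
             i = rep(idx$i, idx$count), j = rep(idx$j, idx$count),
             k = rep(idx$k, idx$count), value = val[[1]])
}

#' Read a simulation configuration from YAML or JSON
#'
#' Scalar and vector keys of [simulation_config()] can be overridden from a
#' key-value file; the remaining defaults are filled in.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path)
         else stop_invalid("config must be YAML or JSON (got .%s)", ext)
  raw <- lapply(raw, function(x) if (is.list(x) && all(lengths(x) == 1) &&
                                       !is.null(names(x))) unlist(x) else x)
  do.call(simulation_config, raw)
}

#' Hash of a configuration (FNV-1a, 8 hex digits)
#' @param config Any R object (serialized to JSON first).
#' @return Character hash.
#' @export
config_hash <- function(config) {
  fnv1a_hash(as.character(jsonlite::toJSON(unclass(config), digits = NA,
                                           force = TRUE, auto_unbox = TRUE)))
}

#' Write a run manifest
#'
#' Every pipeline invocation records stage name, configuration hash, seed,
#' input-file digests, output file list, timestamp and package version,
#' making reruns auditable.
#'
#' @param stage Stage name.
#' @param config The configuration used.
#' @param seed Seed used.
#' @param inputs,outputs Character vectors of file paths.
#' @param path Manifest destination; default `<stage>_manifest.json` next to
#'   the first output.
#' @param extra Named list of extra fields (e.g. masking flags).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(stage, config, seed, inputs = character(0),
                           outputs = character(0), path = NULL,
                           extra = list()) {
  man <- c(list(
    stage = stage,
    config_hash = config_hash(config),
    seed = seed,
    input_digests = stats::setNames(
      lapply(inputs, fnv1a_file), basename(inputs)),
    outputs = basename(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("fixelstats"))),
    extra)
  if (is.null(path))
    path <- file.path(dirname(outputs[1] %||% "."),
                      paste0(stage, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

# ---------------------------------------------------------------------------
# Command-line entry point

cli_usage <- function() {
  paste(
    "usage: fba-pipeline <simulate|phenotype|fba|tracts|predict|all>",
    "                    [--config FILE] [--seed N] [--out DIR]",
    "                    [--mask-lesions | --no-mask-lesions]",
    "                    [--treatment-covariate {none,binary,category}]",
    "                    [--n-permutations N]",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(cmd = NULL, config = NULL, seed = NULL, out = "fba_out",
               mask_lesions = FALSE, treatment = "none",
               n_permutations = 500L)
  if (!length(argv)) stop_invalid("no subcommand given\n%s", cli_usage())
  opts$cmd <- argv[1]
  if (!opts$cmd %in% c("simulate", "phenotype", "fba", "tracts", "predict",
                       "all"))
    stop_invalid("unknown subcommand '%s'\n%s", opts$cmd, cli_usage())
  i <- 2
  take <- function(flag) {
    if (i >= length(argv)) stop_invalid("flag %s needs a value", flag)
    v <- argv[i + 1]; i <<- i + 1; v
  }
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--config") opts$config <- take(a)
    else if (a == "--seed") opts$seed <- as.integer(take(a))
    else if (a == "--out") opts$out <- take(a)
    else if (a == "--mask-lesions") opts$mask_lesions <- TRUE
    else if (a == "--no-mask-lesions") opts$mask_lesions <- FALSE
    else if (a == "--treatment-covariate") {
      opts$treatment <- take(a)
      if (!opts$treatment %in% c("none", "binary", "category"))
        stop_invalid("--treatment-covariate must be none, binary or category")
    }
    else if (a == "--n-permutations") opts$n_permutations <- as.integer(take(a))
    else stop_invalid("unknown flag '%s'\n%s", a, cli_usage())
    i <- i + 1
  }
  opts
}

cli_simulate <- function(cfg, out, coh) {
  paths <- file.path(out, c("cohort.tsv", "template_fixels.tsv",
                            "template_streamlines.jsonl",
                            "tract_metrics.tsv", "cognition.tsv"))
  write_cohort_table(coh$subjects, paths[1])
  write_fixel_template(coh$template, paths[2], paths[3])
  write_tract_table(tract_metric_table(coh), paths[4])
  utils::write.table(coh$cognition, paths[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest("simulate", cfg, cfg$seed, outputs = paths,
                 path = file.path(out, "simulate_manifest.json"))
  coh
}

#' Command-line entry point
#'
#' Thin driver over the package's functions; installed as
#' `inst/scripts/fba-pipeline.R`. Subcommands: `simulate` (write a synthetic
#' cohort), `phenotype` (cognitive profiles), `fba` (whole-brain fixel GLM +
#' CFE), `tracts` (tract-of-interest ANCOVAs), `predict` (nested
#' cross-validated prediction of follow-up cognition), `all`. Every
#' invocation logs the seed and configuration hash and writes a run
#' manifest. Returns the exit status: 0 on success, 2 on validation errors.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
fba_cli <- function(argv) {
  status <- tryCatch({
    opts <- parse_cli_args(argv)
    cfg <- if (!is.null(opts$config)) read_config(opts$config)
           else simulation_config()
    if (!is.null(opts$seed)) cfg$seed <- opts$seed
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    message(sprintf("[fba-pipeline] %s | seed %d | config %s",
                    opts$cmd, cfg$seed, config_hash(cfg)))
    run_phe <- function(coh) {
      prof <- cognitive_profiles(coh)
      p <- file.path(opts$out, "cognitive_profiles.tsv")
      utils::write.table(prof, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_manifest("phenotype", cfg, cfg$seed, outputs = p,
                     path = file.path(opts$out, "phenotype_manifest.json"))
    }
    run_fba <- function(coh) {
      fd <- sapply(coh$fixel_data[vapply(coh$fixel_data, function(r)
        r$timepoint == 1L, TRUE)], function(r) r$fd)
      subj <- coh$subjects[coh$subjects$timepoint == 1L, ]
      subj <- subj[match(colnames(fd), paste0(subj$subject, "|1")), ]
      X <- cbind(1, hc = as.integer(subj$group == "HC"), age = subj$age,
                 head = subj$head_scale)
      res <- permutation_fwe(fd, X, c(0, 1, 0, 0), coh$template,
                             cfe_params(n_permutations = opts$n_permutations,
                                        seed = cfg$seed))
      p <- file.path(opts$out, "fba_fixels.tsv")
      utils::write.table(
        data.frame(fixel_id = coh$template$fixels$fixel_id,
                   tract = coh$template$fixels$tract,
                   t = res$t, e = res$e, p_fwe = res$p_fwe),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      sig <- tapply(res$p_fwe < 0.05, coh$template$fixels$tract, sum)
      p2 <- file.path(opts$out, "fba_tract_counts.tsv")
      utils::write.table(
        data.frame(tract = names(sig), n_significant = as.integer(sig)),
        p2, sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest("fba", cfg, cfg$seed, outputs = c(p, p2),
                     path = file.path(opts$out, "fba_manifest.json"),
                     extra = list(n_permutations = opts$n_permutations))
    }
    run_tracts <- function(coh) {
      tt <- tract_metric_table(coh, mask_lesions = opts$mask_lesions)
      res <- tract_group_analysis(tt, coh$subjects, treatment = opts$treatment)
      p <- file.path(opts$out, "tract_ancova.tsv")
      utils::write.table(res, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_manifest("tracts", cfg, cfg$seed, outputs = p,
                     path = file.path(opts$out, "tracts_manifest.json"),
                     extra = list(masking = opts$mask_lesions,
                                  treatment_covariate = opts$treatment))
    }
    run_predict <- function(coh) {
      tab <- analysis_table(coh)
      feats <- grep("^(fdc|fd|logfc)_", names(tab), value = TRUE)
      ok <- stats::complete.cases(tab[, c(feats, "followup_average_z")])
      res <- nested_cv_predict(tab[ok, feats],
                               tab$followup_average_z[ok], seed = cfg$seed)
      p <- file.path(opts$out, "prediction_report.json")
      jsonlite::write_json(list(
        consistent_features = res$consistent_features,
        train_rmse = res$train_rmse, test_rmse = res$test_rmse,
        test_r = res$test_r,
        adjusted_r2 = res$final$adjusted_r2),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest("predict", cfg, cfg$seed, outputs = p,
                     path = file.path(opts$out, "predict_manifest.json"))
    }
    coh <- generate_cohort(cfg)
    if (opts$cmd %in% c("simulate", "all")) cli_simulate(cfg, opts$out, coh)
    if (opts$cmd %in% c("phenotype", "all")) run_phe(coh)
    if (opts$cmd %in% c("fba", "all")) run_fba(coh)
    if (opts$cmd %in% c("tracts", "all")) run_tracts(coh)
    if (opts$cmd %in% c("predict", "all")) run_predict(coh)
    0L
  },
  fixelstats_validation_error = function(e) {
    message("validation error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Merged analysis table for clinical modelling
#'
#' One row per patient: baseline covariates, volumes and lesion load,
#' baseline tract metrics in wide form (`fd_<tract>`, `logfc_<tract>`,
#' `fdc_<tract>`), baseline and follow-up average cognition and EDSS.
#'
#' @param cohort A `fixel_cohort`.
#' @param mask_lesions Mask lesions when aggregating tract metrics.
#' @return Data frame, patients only.
#' @export
analysis_table <- function(cohort, mask_lesions = FALSE) {
  tt <- tract_metric_table(cohort, mask_lesions = mask_lesions)
  tt <- tt[tt$timepoint == 1L, ]
  wide <- stats::reshape(
    tt[, c("subject", "tract", "mean_fd", "mean_logfc", "mean_fdc")],
    idvar = "subject", timevar = "tract", direction = "wide", sep = ".")
  names(wide) <- sub("^mean_fd\\.", "fd_", names(wide))
  names(wide) <- sub("^mean_logfc\\.", "logfc_", names(wide))
  names(wide) <- sub("^mean_fdc\\.", "fdc_", names(wide))
  prof <- cognitive_profiles(cohort)
  s1 <- cohort$subjects[cohort$subjects$timepoint == 1L, ]
  s2 <- cohort$subjects[cohort$subjects$timepoint == 2L, ]
  out <- s1[s1$group != "HC", ]
  out <- merge(out, wide, by = "subject")
  p1 <- prof[prof$timepoint == 1L, c("subject", "average_z", "class")]
  names(p1) <- c("subject", "baseline_average_z", "baseline_class")
  p2 <- prof[prof$timepoint == 2L, c("subject", "average_z")]
  names(p2) <- c("subject", "followup_average_z")
  e2 <- s2[, c("subject", "edss")]
  names(e2) <- c("subject", "followup_edss")
  out <- merge(out, p1, by = "subject", all.x = TRUE)
  out <- merge(out, p2, by = "subject", all.x = TRUE)
  out <- merge(out, e2, by = "subject", all.x = TRUE)
  out
}
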