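#' Feature assembly for one image at given MNF settings
#'
#' Runs the noise regression at `subimage_size`, fits the MNF transform,
#' denoises at `mnf_cut`, and stacks the requested feature groups: the
#' (denoised) raw bands always, SSV channels if `use_ssv`, pooled
#' Laguerre-Gaussian channels if `use_spatial`.
#'
#' @param cube a [spectral_cube()]
#' @param subimage_size noise-regression tile size in px
#' @param mnf_cut MNF components kept (`NULL` = all)
#' @param use_ssv,use_spatial feature-group toggles
#' @param bank an [build_filter_bank()] bank (required if `use_spatial`)
#' @param regressor noise-regression flavor, see [estimate_noise_residuum()]
#' @return a [feature_stack()]
#' @export
build_features <- function(cube, subimage_size = 30, mnf_cut = NULL,
                           use_ssv = TRUE, use_spatial = FALSE,
                           bank = NULL, regressor = "ols") {
  res <- estimate_noise_residuum(cube, subimage_size, regressor)
  tr <- fit_mnf(cube, res)
  den <- denoise(cube, tr, mnf_cut %||% n_bands(cube))
  parts <- list(raw_band_features(den))
  if (use_ssv) parts <- c(parts, list(ssv_features(res)))
  if (use_spatial) {
    if (is.null(bank)) bank <- build_filter_bank()
    parts <- c(parts, list(extract_lg_features(den, bank)))
  }
  do.call(stack_bind, parts)
}

#' Full-factorial parameter sweep with leave-one-patient-out evaluation
#'
#' Crosses the grid of sub-image sizes, MNF cuts, feature-set toggles and
#' classifiers; features are recomputed per `(subimage_size, mnf_cut)` cell
#' and shared across the toggle/classifier cells that use them. The result
#' is a tidy per-fold table (one row per parameter combination and held-out
#' patient) suitable for external repeated-measures analysis.
#'
#' @param cohort list of `list(cube, mask)` entries (e.g. from
#'   [generate_cohort()]), or a [read_manifest()] result
#' @param grid named list with elements `subimage_size`, `mnf_cut`,
#'   `use_spatial`, `use_ssv`, `classifier`
#' @param seed integer seed for subsampling/classifier fitting
#' @param bank optional [build_filter_bank()]; built on demand when any
#'   `use_spatial` cell is present
#' @param ... passed to [train_eval_lopo()]
#' @return data frame of class `ssv_sweep`
#' @export
run_sweep <- function(cohort,
                      grid = list(subimage_size = c(10, 30),
                                  mnf_cut = c(4, 6),
                                  use_spatial = c(FALSE, TRUE),
                                  use_ssv = c(FALSE, TRUE),
                                  classifier = "random_forest"),
                      seed = 1L, bank = NULL, ...) {
  need <- c("subimage_size", "mnf_cut", "use_spatial", "use_ssv", "classifier")
  miss <- setdiff(need, names(grid))
  if (length(miss)) abort_param("grid lacks: %s", paste(miss, collapse = ", "))
  if (any(!lengths(grid[need]))) abort_param("grid cells must be non-empty")
  if (inherits(cohort, "dataset_manifest")) cohort <- load_cohort(cohort)
  if (is.null(bank) && any(grid$use_spatial)) bank <- build_filter_bank()

  masks <- lapply(cohort, `[[`, "mask")
  out <- list()
  for (ss in grid$subimage_size) for (cut in grid$mnf_cut) {
    # compute shared ingredients once per (ss, cut)
    pieces <- lapply(cohort, function(e) {
      res <- estimate_noise_residuum(e$cube, ss)
      tr <- fit_mnf(e$cube, res)
      den <- denoise(e$cube, tr, min(cut, n_bands(e$cube)))
      list(den = den, res = res)
    })
    for (sp_on in grid$use_spatial) for (ssv_on in grid$use_ssv) {
      stacks <- lapply(pieces, function(p) {
        parts <- list(raw_band_features(p$den))
        if (ssv_on) parts <- c(parts, list(ssv_features(p$res)))
        if (sp_on) parts <- c(parts, list(extract_lg_features(p$den, bank)))
        do.call(stack_bind, parts)
      })
      ds <- dataset_from_stacks(stacks, masks)
      for (cl in grid$classifier) {
        rows <- tryCatch(
          train_eval_lopo(ds, classifier = cl, seed = seed, ...),
          ssv_error = function(e)
            data.frame(held_out_patient = NA_character_, mcc = NA_real_,
                       auc = NA_real_, tp = NA, tn = NA, fp = NA, fn = NA,
                       threshold = NA_real_,
                       status = paste("failed:", conditionMessage(e))))
        rows <- cbind(data.frame(classifier = cl, subimage_size = ss,
                                 mnf_cut = cut, use_spatial = sp_on,
                                 use_ssv = ssv_on), rows)
        out[[length(out) + 1L]] <- rows
      }
    }
  }
  structure(do.call(rbind, out), class = c("ssv_sweep", "data.frame"))
}

load_cohort <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(cube = read_cube(manifest$cube[i]),
         mask = read_mask(manifest$mask[i],
                          patient_id = manifest$patient_id[i],
                          image_id = manifest$image_id[i]))
  })
}

#' @export
print.ssv_sweep <- function(x, ...) {
  cat(sprintf("ssv_sweep: %d rows (%d parameter cells x folds)\n", nrow(x),
              nrow(unique(x[, c("classifier", "subimage_size", "mnf_cut",
                                "use_spatial", "use_ssv")]))))
  agg <- stats::aggregate(cbind(auc, mcc) ~ use_ssv + use_spatial, data = x,
                          FUN = mean, na.rm = TRUE)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write / read a sweep results table as CSV
#'
#' Numeric columns are serialized with `%.17g`, so doubles round-trip
#' exactly and identical configurations + seeds produce byte-identical
#' files.
#'
#' @param x an `ssv_sweep` (or any data frame)
#' @param path CSV path
#' @return `path` / the re-read `ssv_sweep`
#' @export
write_sweep <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) abort_io("no such results file '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("use_spatial", "use_ssv"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  structure(df, class = c("ssv_sweep", "data.frame"))
}
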