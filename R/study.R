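#' Declarative design of a change / no-change comparison study
#'
#' Builds a table of pairwise comparison specifications mirroring the
#' sensitivity/repeatability design: change comparisons vary exactly one
#' stimulation parameter (site, intensity +10 percentage points, or coil
#' angle), no-change comparisons repeat identical parameters on the same day
#' or one week apart. The full-scale shape is 22 site + 20 intensity +
#' 20 angle C comparisons and 10 same-day + 20 one-week NC comparisons; the
#' default here is a scaled-down design that keeps the same proportions.
#'
#' @param n_site,n_intensity,n_angle numbers of C comparisons per parameter.
#' @param n_sameday,n_oneweek numbers of NC comparisons.
#' @param seed master seed from which every per-pair seed is derived.
#' @return data.frame of class `study_design` with one row per comparison:
#'   `id`, `change`, `magnitude`, `base_site`, `intensity_pct`, `day_b`,
#'   `seed_a`, `seed_b`.
#' @export
study_design <- function(n_site = 4, n_intensity = 3, n_angle = 3,
                         n_sameday = 5, n_oneweek = 5, seed = 1L) {
  sites <- c("BA19", "BA7", "BA6")
  site_pairs <- list(c("BA19", "BA6"), c("BA6", "BA7"), c("BA7", "BA19"))
  rows <- list()
  add <- function(change, magnitude, base_site, day_b) {
    i <- length(rows) + 1L
    rows[[i]] <<- data.frame(
      id = sprintf("%s_%02d", ifelse(change == "none",
                                     ifelse(day_b == 1L, "sameday", "oneweek"),
                                     change), i),
      change = change, magnitude = as.character(magnitude),
      base_site = base_site, intensity_pct = 50, day_b = day_b,
      seed_a = derive_seed(seed, paste0("a", i)),
      seed_b = derive_seed(seed, paste0("b", i)),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_site)) {
    p <- site_pairs[[(i - 1L) %% 3L + 1L]]
    add("site", p[2], p[1], 1L)
  }
  for (i in seq_len(n_intensity))
    add("intensity", 10, sites[(i - 1L) %% 3L + 1L], 1L)
  for (i in seq_len(n_angle))
    add("angle", c(45, 90)[(i - 1L) %% 2L + 1L], sites[(i - 1L) %% 3L + 1L], 1L)
  for (i in seq_len(n_sameday))
    add("none", "", sites[(i - 1L) %% 3L + 1L], 1L)
  for (i in seq_len(n_oneweek))
    add("none", "", sites[(i - 1L) %% 3L + 1L], 8L)
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$id)) stop("pair ids not unique")
  class(out) <- c("study_design", class(out))
  out
}

#' Run a comparison study end to end
#'
#' For every row of the design: generate the two synthetic sessions, run the
#' full statistical chain ([compare_sessions()]), and collect the report.
#' Failing comparisons are logged and excluded with an explicit count.
#' Writes the TSV comparison report and a JSON ROC summary (optimal
#' threshold, sensitivity, specificity, accuracy, AUC); re-running with the
#' same design and seed reproduces all numbers.
#'
#' @param design a [study_design()] table.
#' @param outdir output directory (created if missing); `NULL` skips writing.
#' @param alpha,n_perm,seed statistical configuration (seed only stamps the
#'   report; per-pair randomness comes from the design's seeds).
#' @param n_trials trials per synthetic session.
#' @param min_trials trial floor for the evoked average (scaled with
#'   `n_trials`; the full-scale floor is 150 of ~200).
#' @param config extra [session_config()] arguments (noise, artifacts, ...).
#' @param ... extra arguments passed to [compare_sessions()].
#' @return list of class `study_result`: `records` (data.frame), `roc`
#'   ([roc_curve()] over total DIs), `failures` (named error messages),
#'   `paths` (written files).
#' @export
run_study <- function(design, outdir = NULL, alpha = 0.05, n_perm = 500,
                      seed = 1L, n_trials = 160,
                      min_trials = max(2, round(0.75 * n_trials)),
                      config = list(), ...) {
  stopifnot(inherits(design, "study_design") || is.data.frame(design))
  records <- list()
  failures <- character()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    res <- tryCatch({
      cfg <- do.call(session_config, utils::modifyList(
        list(site = row$base_site, intensity_pct = row$intensity_pct,
             n_trials = n_trials, seed = row$seed_a), config))
      mag <- switch(row$change,
                    site = row$magnitude,
                    intensity = as.numeric(row$magnitude),
                    angle = as.numeric(row$magnitude),
                    none = NULL)
      pair <- make_comparison_pair(cfg, change = row$change, magnitude = mag,
                                   seeds = c(row$seed_a, row$seed_b),
                                   day_b = row$day_b)
      compare_sessions(pair$a, pair$b, comparison_id = row$id,
                       alpha = alpha, n_perm = n_perm,
                       seed = derive_seed(seed, row$id),
                       min_trials = min_trials, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[row$id] <- conditionMessage(res)
    } else {
      records[[row$id]] <- res$record
    }
  }
  if (length(failures))
    message(length(failures), " of ", nrow(design),
            " comparisons failed and were excluded: ",
            paste(names(failures), collapse = ", "))
  if (!length(records)) stop("every comparison failed; nothing to report")
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  roc <- if (length(unique(records$label)) == 2L)
    roc_curve(records$DI_total, records$label) else NULL

  paths <- character()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    report_path <- file.path(outdir, "comparisons.tsv")
    write_report(records, report_path)
    paths["report"] <- report_path
    if (!is.null(roc)) {
      roc_path <- file.path(outdir, "roc_summary.json")
      jsonlite::write_json(
        list(optimal_threshold = roc$optimal_threshold,
             sensitivity = roc$sensitivity, specificity = roc$specificity,
             accuracy = roc$accuracy, auc = roc$auc,
             n_C = roc$n_C, n_NC = roc$n_NC,
             alpha = alpha, n_perm = n_perm, seed = seed,
             n_failures = length(failures)),
        roc_path, auto_unbox = TRUE, digits = NA)
      paths["roc"] <- roc_path
    }
    if (length(failures)) {
      log_path <- file.path(outdir, "failures.log")
      writeLines(paste(names(failures), failures, sep = "\t"), log_path)
      paths["failures"] <- log_path
    }
  }
  structure(list(records = records, roc = roc, failures = failures,
                 paths = paths,
                 config = list(alpha = alpha, n_perm = n_perm, seed = seed,
                               n_trials = n_trials, min_trials = min_trials)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d comparisons (%d C, %d NC), %d failures\n",
              nrow(x$records), sum(x$records$label == "C"),
              sum(x$records$label == "NC"), length(x$failures)))
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}
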