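# let data.table find its symbols when called through ::
.datatable.aware <- TRUE

#' Filter raw trials and aggregate to binomial cells
#'
#' Drops trials without a response, then trials with a fixation break, and
#' aggregates the remainder into binomial cells (one row per
#' participant x image x image_type x comparison x model x scale with
#' `n_trials` and `n_correct`). The filtering order affects only the
#' per-rule attribution in the report, never the retained set.
#'
#' @param raw data.frame of raw trials with columns participant, image,
#'   image_type, comparison, model, scale, response (NA = no response),
#'   correct (logical/0-1), fixation_break (logical/0-1).
#' @param cell_keys grouping columns for aggregation; the second
#'   experiment's tables substitute `radius` for `scale` — pass
#'   `cell_keys` accordingly.
#' @return list with `table` (aggregated trial table) and `report` (counts:
#'   `n_input`, `dropped` per rule, `n_retained`).
#' @export
filter_trials <- function(raw,
                          cell_keys = c("participant", "image",
                                        "image_type", "comparison",
                                        "model", "scale")) {
  req <- unique(c(cell_keys, "response", "correct", "fixation_break"))
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("raw trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_input <- nrow(raw)
  no_resp <- is.na(raw$response)
  step1 <- raw[!no_resp, , drop = FALSE]
  fb <- as.logical(step1$fixation_break)
  kept <- step1[!fb, , drop = FALSE]
  report <- list(n_input = n_input,
                 dropped = list(no_response = sum(no_resp),
                                fixation_break = sum(fb)),
                 n_retained = nrow(kept))
  if (nrow(kept) == 0) {
    tab <- kept[, cell_keys, drop = FALSE]
    tab$n_trials <- integer(0); tab$n_correct <- integer(0)
    return(list(table = tab, report = report))
  }
  dt <- data.table::as.data.table(kept)
  agg <- dt[, list(n_trials = .N, n_correct = sum(as.logical(correct))),
            by = cell_keys]
  list(table = as.data.frame(agg), report = report)
}

#' Read a raw trial CSV through a schema adapter
#'
#' Column names vary between data dialects; the adapter maps them onto
#' the package's canonical names and passes unknown extra columns through
#' untouched.
#'
#' @param path CSV path.
#' @param schema `"default"` (canonical names already) or a named
#'   character vector `c(canonical = "file_column", ...)`.
#' @return data.frame of raw trials.
#' @export
read_trials_csv <- function(path, schema = "default") {
  d <- as.data.frame(data.table::fread(path))
  if (!identical(schema, "default")) {
    hit <- schema[schema %in% names(d)]
    names(d)[match(hit, names(d))] <- names(hit)
  }
  d
}

#' Proportion correct by condition, observer-mean style
#'
#' Computes each observer's proportion correct within each group, then the
#' across-observer mean and standard error of that mean. Groups with zero
#' trials are excluded; a single-observer group gets `sem = NA`.
#'
#' @param table aggregated trial table (columns `n_trials`, `n_correct`,
#'   `participant`, plus the grouping columns).
#' @param group_keys character vector of grouping columns.
#' @return data.frame with the group keys, `n_observers`, `pc` (mean of
#'   observer means) and `sem`.
#' @export
pc_by_condition <- function(table, group_keys) {
  miss <- setdiff(c(group_keys, "participant", "n_trials", "n_correct"),
                  names(table))
  if (length(miss))
    stop("table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(table)
  obs <- dt[, list(pc_obs = sum(n_correct) / sum(n_trials),
                   nt = sum(n_trials)),
            by = c(group_keys, "participant")]
  obs <- obs[obs$nt > 0, ]
  out <- obs[, list(n_observers = .N, pc = mean(pc_obs),
                    sem = if (.N > 1) stats::sd(pc_obs) / sqrt(.N)
                          else NA_real_),
             by = group_keys]
  as.data.frame(out)
}

#' Write an aggregated trial table / filter report
#' @param table trial table data.frame.
#' @param report a filter report from [filter_trials()].
#' @param path output path.
#' @export
write_trials_csv <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
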