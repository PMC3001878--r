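# Plain-text interchange: trial tables as CSV (with a JSON sidecar carrying
# metadata) and posteriors/comparisons as JSON. Numeric round-trips use 17
# significant digits, which is lossless for doubles.

fmt17 <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else sprintf("%.17g", v), character(1))
  out
}

meta_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

#' Write trial data to CSV (plus JSON sidecar)
#'
#' Columns are `trial` (0-based), `input_1..input_J` (trials with fewer
#' inputs are right-padded with empty fields) and `response_1..response_K`;
#' missing responses are empty fields. Metadata and channel labels go to a
#' `.meta.json` sidecar next to the CSV.
#'
#' @param data a [trial_data()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  tt <- length(data$inputs)
  jmax <- max(lengths(data$inputs), 1L)
  kk <- ncol(data$responses)
  inp <- t(vapply(data$inputs, function(u) {
    c(u, rep(NA_real_, jmax - length(u)))
  }, numeric(jmax)))
  if (jmax == 1L) inp <- matrix(inp, ncol = 1L)
  m <- cbind(matrix(as.character(0:(tt - 1L)), ncol = 1),
             matrix(fmt17(inp), nrow = tt),
             matrix(fmt17(data$responses), nrow = tt))
  header <- c("trial", paste0("input_", seq_len(jmax)),
              paste0("response_", seq_len(kk)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(m, 1, paste, collapse = ","), con)
  jsonlite::write_json(list(labels = data$labels, meta = data$meta),
                       meta_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read trial data from CSV
#'
#' Inverse of [write_trials()]: `read_trials(write_trials(x, p))` reproduces
#' `x` field-for-field. Unknown extra columns are preserved in
#' `meta$extra_columns` with a warning; malformed cells raise a parse error
#' naming the row and column.
#'
#' @param path CSV file path.
#' @return a [trial_data()].
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0)
    ibdt_stop("trial file contains no trials", "ibdt_parse_error")
  cols <- names(df)
  if (!"trial" %in% cols)
    ibdt_stop("missing required column 'trial'", "ibdt_parse_error")
  in_cols <- grep("^input_[0-9]+$", cols, value = TRUE)
  re_cols <- grep("^response_[0-9]+$", cols, value = TRUE)
  if (length(in_cols) == 0 || length(re_cols) == 0)
    ibdt_stop("missing input_*/response_* columns", "ibdt_parse_error")
  extra <- setdiff(cols, c("trial", in_cols, re_cols))
  if (length(extra) > 0)
    warning("unknown columns preserved in meta: ", paste(extra, collapse = ", "))
  parse_num <- function(col) {
    raw <- df[[col]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
    if (length(bad) > 0)
      ibdt_stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                        bad[1], col, raw[bad[1]]), "ibdt_parse_error")
    out[!nzchar(raw)] <- NA_real_
    out
  }
  inp <- sapply(in_cols[order(as.integer(sub("input_", "", in_cols)))],
                parse_num)
  if (is.null(dim(inp))) inp <- matrix(inp, nrow = nrow(df))
  resp <- sapply(re_cols[order(as.integer(sub("response_", "", re_cols)))],
                 parse_num)
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = nrow(df))
  colnames(resp) <- NULL
  inputs <- lapply(seq_len(nrow(df)), function(t) {
    row <- inp[t, ]
    keep <- rev(cumsum(rev(!is.na(row)))) > 0  # strip trailing padding only
    as.numeric(row[keep])
  })
  meta <- list()
  labels <- NULL
  mp <- meta_path(path)
  if (file.exists(mp)) {
    side <- jsonlite::read_json(mp, simplifyVector = TRUE)
    meta <- side$meta
    labels <- side$labels
  }
  if (length(extra) > 0)
    meta$extra_columns <- df[extra]
  trial_data(inputs, resp, labels = labels, meta = meta)
}

#' Serialize an experimenter posterior to JSON
#'
#' Writes parameter names, mode, covariance, free energy, residuals, noise
#' variance, convergence information and metadata at full precision;
#' [posterior_from_json()] round-trips the numeric content.
#'
#' @param post an `experimenter_posterior`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
posterior_to_json <- function(post, path) {
  obj <- list(
    package = "ibdt", version = as.character(utils::packageVersion("ibdt")),
    parameter_names = names(post$mode),
    mode = as.numeric(post$mode),
    covariance = unclass(post$covariance),
    free_energy = post$free_energy,
    loglik_at_mode = post$loglik_at_mode,
    residuals = unclass(post$residuals),
    noise_variance = post$noise_variance,
    theta_hat = as.list(post$theta_hat),
    phi_hat = as.list(post$phi_hat),
    prior = list(mean = post$prior$mean, covariance = unclass(post$prior$covariance),
                 noise = post$prior$noise),
    converged = post$converged,
    meta = post$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname posterior_to_json
#' @export
posterior_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$mode <- stats::setNames(as.numeric(obj$mode), obj$parameter_names)
  obj$covariance <- as.matrix(obj$covariance)
  obj$residuals <- as.matrix(obj$residuals)
  obj
}
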