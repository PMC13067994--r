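#' Construct an intensive-longitudinal (EMA) dataset
#'
#' Bundles long-format respondent-by-occasion observations into a validated
#' container: one row per completed questionnaire, with a respondent
#' identifier, an occasion index, a timestamp in hours since study start,
#' `J` ordinal item responses coded `0..G` (missing allowed), and optional
#' covariate columns. Between-occasion intervals (in hours) are always
#' recomputed from the timestamps, never read from the file, so they cannot
#' drift out of sync.
#'
#' @param data data.frame in long format.
#' @param items character vector of item column names (responses `0..G`).
#' @param id,occasion,time names of the respondent-identifier, occasion-index
#'   and timestamp (hours) columns.
#' @param covariates character vector of covariate column names (may be
#'   empty). Person-level covariates are simply repeated across a person's
#'   rows.
#' @param n_categories number of response categories `G + 1`. Defaults to
#'   `max(response) + 1` over the non-missing responses.
#' @return An object of class `ema_dataset`: a list with the sorted data
#'   (including a computed `.delta` interval column, `NA` on each
#'   respondent's first row), item/covariate names and size metadata.
#' @examples
#' df <- data.frame(id = 1, occasion = 1:2, time_hours = c(8, 9.5),
#'                  it1 = c(0, 3), it2 = c(2, 6))
#' d <- ema_dataset(df, items = c("it1", "it2"), n_categories = 7)
#' d$data$.delta  # NA, 1.5
#' @export
ema_dataset <- function(data, items, id = "id", occasion = "occasion",
                        time = "time_hours", covariates = character(),
                        n_categories = NULL) {
  stopifnot(is.data.frame(data))
  needed <- c(id, occasion, time, items, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  df <- data[order(data[[id]], data[[time]]), , drop = FALSE]
  rownames(df) <- NULL

  resp <- as.matrix(df[, items, drop = FALSE])
  storage.mode(resp) <- "double"
  nonmiss <- resp[!is.na(resp)]
  if (length(nonmiss) == 0L) stop("no non-missing responses in the data")
  if (any(nonmiss != round(nonmiss)))
    stop("non-integer response codes found")
  if (is.null(n_categories)) n_categories <- as.integer(max(nonmiss)) + 1L
  bad <- which(!is.na(resp) & (resp < 0 | resp > n_categories - 1L),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("response out of range [0, %d] at row %d, column '%s'",
                 n_categories - 1L, bad[1, 1], items[bad[1, 2]]))

  all_missing <- rowSums(!is.na(resp)) == 0L
  if (any(all_missing)) {
    warning(sprintf("dropping %d rows with all items missing",
                    sum(all_missing)))
    df <- df[!all_missing, , drop = FALSE]
    rownames(df) <- NULL
  }

  rid <- as.factor(df[[id]])
  tm <- as.numeric(df[[time]])
  if (any(!is.finite(tm)) || any(tm < 0))
    stop("timestamps must be finite nonnegative hours")
  delta <- ave(tm, rid, FUN = function(x) c(NA_real_, diff(x)))
  if (any(delta <= 0, na.rm = TRUE)) {
    i <- which(delta <= 0)[1]
    stop(sprintf("non-increasing timestamps within respondent '%s' (row %d)",
                 as.character(rid[i]), i))
  }
  df$.delta <- delta

  structure(list(
    data = df, items = items, id = id, occasion = occasion, time = time,
    covariates = covariates,
    n_respondents = nlevels(rid),
    n_items = length(items),
    n_categories = as.integer(n_categories),
    n_obs = nrow(df)
  ), class = "ema_dataset")
}

#' @export
print.ema_dataset <- function(x, ...) {
  cat(sprintf(
    "ema_dataset: %d observations, %d respondents, %d items, %d categories\n",
    x$n_obs, x$n_respondents, x$n_items, x$n_categories))
  if (length(x$covariates))
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# Integer response matrix with NA for missing (for the compiled kernels).
response_matrix <- function(dataset) {
  m <- as.matrix(dataset$data[, dataset$items, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Read a long-format EMA data file
#'
#' Reads comma-separated long-format data and validates it into an
#' [ema_dataset()]. Missing responses may be empty cells or the string
#' `"NA"`; internally they are a mask, never a category code. Responses are
#' 0-based; 1-based files must declare `base = 1` in the schema and are
#' shifted on read.
#'
#' @param path file path.
#' @param schema named list mapping roles to column names: `id`, `occasion`,
#'   `time`, `items` (character vector), optional `covariates`, optional
#'   `base` (0 or 1, default 0) and optional `n_categories`.
#' @return An [ema_dataset()].
#' @export
read_ema_data <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.list(schema), !is.null(schema$items))
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  base <- if (is.null(schema$base)) 0L else as.integer(schema$base)
  if (!base %in% c(0L, 1L)) stop("schema$base must be 0 or 1")
  for (it in schema$items) {
    v <- df[[it]]
    if (is.null(v)) stop("item column not in file: ", it)
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (any(!is.na(df[[it]]) & is.na(v)))
      stop("non-numeric response codes in column '", it, "'")
    df[[it]] <- v - base
  }
  ema_dataset(df,
              items = schema$items,
              id = if (is.null(schema$id)) "id" else schema$id,
              occasion = if (is.null(schema$occasion)) "occasion" else schema$occasion,
              time = if (is.null(schema$time)) "time_hours" else schema$time,
              covariates = if (is.null(schema$covariates)) character() else schema$covariates,
              n_categories = schema$n_categories)
}

#' Write and re-read fitted model artifacts
#'
#' Serializes a step-1 mixture fit (or a step-3 transition model) to plain
#' text: parameter tables as CSV, scalar metadata and convergence trace as
#' JSON, posteriors as one CSV row per observation. The round trip is
#' lossless to full double precision.
#'
#' @param fit a `mixture_fit` or `transition_model` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(fit, dir) {
  if (is.null(fit)) stop("empty fit: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(fit, "mixture_fit")) {
    att <- data.frame(item = seq_len(nrow(fit$attentive$loadings)),
                      loading = fit$attentive$loadings[, 1],
                      fit$attentive$thresholds)
    names(att)[-(1:2)] <- paste0("kappa", seq_len(ncol(fit$attentive$thresholds)))
    write.csv(format(att, digits = 17, trim = TRUE),
              file.path(dir, "attentive_params.csv"), row.names = FALSE,
              quote = FALSE)
    cier <- data.frame(t(c(sigma2_xi = fit$cier$sigma2_xi,
                           stats::setNames(fit$cier$thresholds,
                                           paste0("kappa", seq_along(fit$cier$thresholds))))))
    write.csv(format(cier, digits = 17, trim = TRUE),
              file.path(dir, "cier_params.csv"), row.names = FALSE, quote = FALSE)
    post <- data.frame(p_attentive = fit$posterior[, 1],
                       p_cier = fit$posterior[, 2])
    write.csv(format(post, digits = 17, trim = TRUE),
              file.path(dir, "posteriors.csv"), row.names = FALSE, quote = FALSE)
    meta <- list(pi2 = fit$pi2, loglik = fit$loglik, converged = fit$converged,
                 n_iter = fit$n_iter, best_start = fit$best_start,
                 n_replicated = fit$n_replicated,
                 n_quad = fit$settings$n_quad,
                 quad_range = fit$settings$quad_range,
                 loglik_trace = fit$loglik_trace)
    jsonlite::write_json(meta, file.path(dir, "mixture_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- file.path(dir, c("attentive_params.csv", "cier_params.csv",
                              "posteriors.csv", "mixture_meta.json"))
  } else if (inherits(fit, "transition_model")) {
    jsonlite::write_json(
      list(beta = fit$beta, gamma12 = fit$gamma12, gamma21 = fit$gamma21,
           covariates = fit$covariates, loglik = fit$loglik,
           D = fit$D, vcov = fit$vcov, par_names = fit$par_names),
      file.path(dir, "transition_model.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    files <- file.path(dir, "transition_model.json")
  } else stop("unsupported fit object of class ", paste(class(fit), collapse = "/"))
  invisible(files)
}

#' @rdname write_results
#' @export
read_mixture_fit <- function(dir) {
  att <- read.csv(file.path(dir, "attentive_params.csv"))
  cier <- read.csv(file.path(dir, "cier_params.csv"))
  post <- as.matrix(read.csv(file.path(dir, "posteriors.csv")))
  meta <- jsonlite::read_json(file.path(dir, "mixture_meta.json"),
                              simplifyVector = TRUE)
  kcols <- grep("^kappa", names(att))
  fit <- list(
    attentive = attentive_grm(loadings = matrix(att$loading, ncol = 1),
                              thresholds = as.matrix(att[, kcols])),
    cier = cier_grm(thresholds = as.numeric(cier[grep("^kappa", names(cier))]),
                    sigma2_xi = cier$sigma2_xi),
    pi2 = meta$pi2, posterior = cbind(post[, 1], post[, 2]),
    loglik = meta$loglik, converged = meta$converged, n_iter = meta$n_iter,
    best_start = meta$best_start, n_replicated = meta$n_replicated,
    loglik_trace = meta$loglik_trace,
    settings = estimation_settings(
      n_quad = if (is.null(meta$n_quad)) 61 else meta$n_quad,
      quad_range = if (is.null(meta$quad_range)) 6 else meta$quad_range))
  colnames(fit$posterior) <- c("p_attentive", "p_cier")
  class(fit) <- "mixture_fit"
  fit
}
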