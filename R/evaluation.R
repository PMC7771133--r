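#' Spearman rank correlation
#'
#' Rank correlation between behavioral performance and model distances:
#' Pearson correlation of average ranks (the standard tie treatment). Inputs
#' must have equal length of at least 3; a constant vector has undefined rank
#' correlation and is an error rather than an NA.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return rho in \[-1, 1\]
#' @examples
#' spearman_rho(1:4, c(2, 1, 4, 3)) # 0.6
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values", call. = FALSE)
  if (max(x) == min(x) || max(y) == min(y)) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(rank(x), rank(y))
}

#' Read a behavioral discrimination dataset
#'
#' CSV with columns `pair, stimA, stimB, prop_correct` and optionally
#' precomputed distance columns `dist_<model>`. Proportions must lie in
#' \[0, 1\] and pair ids must be unique.
#'
#' @param path CSV path
#' @return data.frame of class `behavioral_data`
#' @export
read_behavior <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  behavioral_data(df)
}

#' @rdname read_behavior
#' @param df data.frame with the columns above
#' @export
behavioral_data <- function(df) {
  need <- c("pair", "stimA", "stimB", "prop_correct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing behavioral columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  p <- df$prop_correct
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("prop_correct must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df$pair)) stop("pair ids must be unique", call. = FALSE)
  class(df) <- c("behavioral_data", "data.frame")
  df
}

#' Average reciprocal target/background records
#'
#' In detection experiments each color pair is often run twice with the roles
#' of target and background swapped; when distances and performance are
#' role-symmetric the two records can be averaged before correlation. Rows
#' whose unordered stimulus set {stimA, stimB} coincides are collapsed to one
#' row with the mean `prop_correct` (and the mean of any `dist_*` columns,
#' which for symmetric distance measures are identical anyway).
#'
#' @param data [behavioral_data()]
#' @return [behavioral_data()] with one row per unordered pair
#' @export
average_reciprocal <- function(data) {
  stopifnot(inherits(data, "behavioral_data"))
  key <- apply(cbind(as.character(data$stimA), as.character(data$stimB)), 1L,
               function(r) paste(sort(r), collapse = "|"))
  num_cols <- c("prop_correct", grep("^dist_", names(data), value = TRUE))
  pieces <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    row <- data[idx[1L], , drop = FALSE]
    for (cc in num_cols) row[[cc]] <- mean(data[[cc]][idx])
    row
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  behavioral_data(as.data.frame(out))
}

resolve_distances <- function(data, provider, model_name) {
  if (is.numeric(provider)) {
    if (length(provider) != nrow(data)) {
      stop(sprintf("model '%s': %d distances for %d pairs", model_name,
                   length(provider), nrow(data)), call. = FALSE)
    }
    return(as.numeric(provider))
  }
  if (is.character(provider) && length(provider) == 1L) {
    col <- if (provider %in% names(data)) provider else paste0("dist_", provider)
    if (!col %in% names(data)) {
      stop(sprintf("model '%s': no distance column '%s' in behavioral data",
                   model_name, provider), call. = FALSE)
    }
    return(as.numeric(data[[col]]))
  }
  if (is.function(provider)) {
    d <- mapply(provider, as.character(data$stimA), as.character(data$stimB))
    if (anyNA(d)) {
      stop(sprintf("model '%s': unresolvable pair", model_name), call. = FALSE)
    }
    return(as.numeric(d))
  }
  stop(sprintf("model '%s': provider must be a numeric vector, column name, or function(stimA, stimB)",
               model_name), call. = FALSE)
}

#' Rank models by correlation with behavioral performance
#'
#' For each model, resolves a distance for every stimulus pair and computes
#' Spearman's rho between proportion correct and distance; models are then
#' ranked by rho (larger is better; ties share the better rank). A model's
#' distances may be given as a numeric vector aligned with the rows of
#' `data`, the name of a `dist_<model>` column in `data`, or a function
#' `f(stimA, stimB)` returning the distance for one pair (e.g. a closure over
#' [nsc_locus()] objects).
#'
#' @param data [behavioral_data()]
#' @param models named list of distance providers
#' @param average_reciprocal collapse reciprocal target/background records
#'   first? (default FALSE)
#' @return object of class `model_comparison`: data.frame with columns
#'   `model`, `rho`, `rank`, ordered by decreasing rho (name as tie-break for
#'   a deterministic ordering; the `rank` column exposes ties)
#' @export
compare_models <- function(data, models, average_reciprocal = FALSE) {
  stopifnot(inherits(data, "behavioral_data"))
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be a named list", call. = FALSE)
  }
  if (average_reciprocal) data <- nscolor::average_reciprocal(data)
  rho <- vapply(names(models), function(m) {
    d <- resolve_distances(data, models[[m]], m)
    spearman_rho(data$prop_correct, d)
  }, numeric(1L))
  out <- data.frame(model = names(models), rho = unname(rho),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$rho, ties.method = "min")
  out <- out[order(-out$rho, out$model), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model ranking by Spearman rho (performance vs distance):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
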