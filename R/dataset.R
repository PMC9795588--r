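#' Construct a two-arm observational dataset
#'
#' Bundles the `(X, T, Y)` triple for one two-arm comparison: an `n x d`
#' matrix of baseline covariates, a binary treatment indicator (1 =
#' experimental arm, 0 = control/external arm) and a continuous outcome.
#' The package works under a complete-case contract: missing values are
#' rejected at construction.
#'
#' @param X numeric matrix of baseline covariates (`n x d`).
#' @param t binary treatment indicator of length `n`.
#' @param y numeric outcome of length `n`.
#' @return an object of class `eca_dataset` with elements `X`, `t`, `y`.
#' @export
eca_dataset <- function(X, t, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  t <- as.integer(t)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(t) != n || length(y) != n)
    stop("X, t and y must describe the same number of patients")
  if (anyNA(X) || anyNA(t) || anyNA(y))
    stop("missing values are not supported (complete-case contract)")
  if (!all(t %in% c(0L, 1L)))
    stop("t must be binary (0 = control, 1 = experimental)")
  if (sum(t == 1L) < 2L || sum(t == 0L) < 2L)
    stop("each arm needs at least 2 patients")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, t = t, y = y), class = "eca_dataset")
}

#' @export
print.eca_dataset <- function(x, ...) {
  cat(sprintf(
    "<eca_dataset> n = %d (treated %d / control %d), d = %d covariates\n",
    length(x$t), sum(x$t == 1L), sum(x$t == 0L), ncol(x$X)
  ))
  invisible(x)
}

#' Write a dataset to CSV
#'
#' Column layout is `y,t,x1,...,xd` with one row per patient, `t` coded
#' 0/1, UTF-8 and `.` as the decimal separator. Output is byte-stable for
#' identical inputs.
#'
#' @param dataset an [eca_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "eca_dataset"))
  df <- data.frame(y = dataset$y, t = dataset$t, dataset$X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param path CSV file path with columns `y,t,x1,...,xd`.
#' @return an [eca_dataset()].
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("y", "t") %in% names(df)))
    stop("expected columns 'y' and 't' in ", path)
  xcols <- setdiff(names(df), c("y", "t"))
  eca_dataset(as.matrix(df[, xcols, drop = FALSE]), df$t, df$y)
}

# Row-subset a dataset without revalidating arm sizes (bootstrap internals
# check degeneracy themselves).
dataset_rows <- function(dataset, idx) {
  structure(
    list(X = dataset$X[idx, , drop = FALSE],
         t = dataset$t[idx], y = dataset$y[idx]),
    class = "eca_dataset"
  )
}
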