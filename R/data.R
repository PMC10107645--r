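#' Partly interval-censored survival data with time-varying covariates
#'
#' Constructs the internal representation of a partly interval-censored
#' dataset from a long-format (counting-process style) data frame with one
#' row per interval of covariate constancy. Required columns:
#'
#' * `id` — subject identifier;
#' * `tstart`, `tstop` — endpoints of the covariate-constancy interval
#'   (`tstart` of the first row must be 0, rows must be contiguous, and
#'   the last `tstop` must equal the subject's largest finite censoring
#'   endpoint);
#' * `yL`, `yR` — the observed censoring interval (`yR` is `Inf` for
#'   right-censored subjects);
#' * `censor_type` — one of `"event"` (`yL == yR`), `"right"`
#'   (`yR == Inf`), `"left"` (`yL == 0`), `"interval"`
#'   (`0 < yL < yR < Inf`);
#' * time-fixed covariate columns (default: names starting with `x`),
#'   constant within subject;
#' * time-varying covariate columns (default: names starting with `z`),
#'   piecewise constant with the convention \eqn{z(t) = z_{ia}} on
#'   \eqn{[t_{ia}, t_{i,a+1})} and the last value carried forward beyond
#'   the final change time.
#'
#' @param df a data frame in the long format described above.
#' @param x_cols,z_cols character vectors naming the time-fixed and
#'   time-varying covariate columns; by default, columns whose names start
#'   with `"x"` and `"z"` respectively.
#' @return An object of class `tvc_data`.
#' @seealso [read_tvc()], [write_tvc()], [covariate_at()]
#' @export
tvc_data <- function(df, x_cols = NULL, z_cols = NULL) {
  df <- as.data.frame(df)
  need <- c("id", "tstart", "tstop", "yL", "yR", "censor_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(x_cols)) x_cols <- grep("^x", names(df), value = TRUE)
  if (is.null(z_cols)) z_cols <- grep("^z", names(df), value = TRUE)
  if (nrow(df) == 0L) stop("empty dataset")

  types <- c("event", "right", "left", "interval")
  if (!all(df$censor_type %in% types))
    stop("censor_type must be one of: ", paste(types, collapse = ", "))
  df$yR[is.na(df$yR)] <- Inf

  ids <- unique(df$id)
  n <- length(ids)
  sid_row <- match(df$id, ids)
  ord <- order(sid_row, df$tstart)
  df <- df[ord, , drop = FALSE]
  sid_row <- sid_row[ord]

  first <- !duplicated(sid_row)
  sub <- df[first, c("id", "yL", "yR", "censor_type"), drop = FALSE]
  rownames(sub) <- NULL

  # per-subject consistency of censoring interval and covariates
  for (cl in c("yL", "yR", "censor_type", x_cols)) {
    v <- df[[cl]]
    ref <- v[first][sid_row]
    same <- ifelse(is.na(v) & is.na(ref), TRUE, v == ref)
    if (!all(same, na.rm = FALSE))
      stop("column '", cl, "' varies within a subject (id ",
           df$id[which(!same)[1]], ")")
  }

  tol <- 1e-8
  y <- numeric(n)
  for (i in seq_len(n)) {
    yL <- sub$yL[i]; yR <- sub$yR[i]; ty <- sub$censor_type[i]
    bad <- switch(ty,
      event    = !(is.finite(yL) && yL == yR && yL > 0),
      right    = !(is.finite(yL) && is.infinite(yR)),
      left     = !(yL == 0 && is.finite(yR) && yR > 0),
      interval = !(yL > 0 && is.finite(yR) && yL < yR))
    if (bad)
      stop("censor_type '", ty, "' inconsistent with (yL, yR) for id ",
           sub$id[i])
    y[i] <- if (ty == "right") yL else if (ty == "event") yL else yR
  }

  # contiguity of covariate-constancy intervals
  tstart <- df$tstart; tstop <- df$tstop
  for (i in seq_len(n)) {
    rows <- which(sid_row == i)
    s <- tstart[rows]; e <- tstop[rows]
    if (abs(s[1]) > tol)
      stop("first interval for id ", sub$id[i], " must start at 0")
    if (any(e <= s + 0))
      stop("empty or reversed interval for id ", sub$id[i],
           " (row ", rows[which(e <= s)[1]], ")")
    if (length(rows) > 1L && any(abs(s[-1] - e[-length(e)]) > tol))
      stop("overlapping or gapped intervals for id ", sub$id[i],
           " (row ", rows[1 + which(abs(s[-1] - e[-length(e)]) > tol)[1]], ")")
    if (abs(e[length(e)] - y[i]) > max(tol, tol * y[i]))
      stop("last interval for id ", sub$id[i],
           " must end at the largest finite censoring endpoint (",
           format(y[i]), ")")
  }

  X <- as.matrix(df[first, x_cols, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- as.matrix(df[, z_cols, drop = FALSE])
  storage.mode(Z) <- "double"
  if (anyNA(X) || anyNA(Z)) stop("missing covariate values are not supported")

  structure(list(
    subjects = data.frame(id = sub$id, yL = sub$yL, yR = sub$yR,
                          censor_type = sub$censor_type, y = y,
                          stringsAsFactors = FALSE),
    X = X, Z = Z,
    sid = sid_row, tstart = tstart, tstop = tstop,
    x_cols = x_cols, z_cols = z_cols,
    n = n, p = ncol(X), q = ncol(Z), N = nrow(df)),
    class = "tvc_data")
}

#' @export
print.tvc_data <- function(x, ...) {
  tab <- table(factor(x$subjects$censor_type,
                      levels = c("event", "right", "left", "interval")))
  cat("Partly interval-censored dataset: ", x$n, " subjects, ",
      x$N, " covariate intervals\n", sep = "")
  cat("  censoring: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  time-fixed covariates: ",
      if (x$p) paste(x$x_cols, collapse = ", ") else "none", "\n", sep = "")
  cat("  time-varying covariates: ",
      if (x$q) paste(x$z_cols, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tvc_data <- function(x, ...) {
  sub <- x$subjects[x$sid, , drop = FALSE]
  out <- data.frame(id = sub$id, tstart = x$tstart, tstop = x$tstop,
                    yL = sub$yL, yR = sub$yR,
                    censor_type = sub$censor_type,
                    stringsAsFactors = FALSE)
  Xl <- x$X[x$sid, , drop = FALSE]
  for (j in seq_len(x$p)) out[[x$x_cols[j]]] <- Xl[, j]
  for (j in seq_len(x$q)) out[[x$z_cols[j]]] <- x$Z[, j]
  rownames(out) <- NULL
  out
}

#' Time-varying covariate value at a given time
#'
#' Looks up the piecewise-constant covariate vector of one subject at time
#' `t` using the left-closed convention \eqn{z(t) = z_{ia}} for
#' \eqn{t \in [t_{ia}, t_{i,a+1})}; beyond the last change time the last
#' value is carried forward.
#'
#' @param data a [tvc_data()] object.
#' @param id subject identifier.
#' @param t a single non-negative time.
#' @return the `q`-vector of covariate values at `t`.
#' @export
covariate_at <- function(data, id, t) {
  if (t < 0) stop("'t' must be non-negative")
  i <- match(id, data$subjects$id)
  if (is.na(i)) stop("unknown subject id: ", id)
  rows <- which(data$sid == i)
  a <- findInterval(t, data$tstart[rows])
  if (a < 1L) a <- 1L
  drop(data$Z[rows[a], ])
}

#' Read / write the long-format CSV dialect
#'
#' `read_tvc()` reads a comma-separated file with a header row containing
#' the columns described in [tvc_data()]; an empty field or the string
#' `"Inf"` in `yR` denotes an infinite (right-censoring) endpoint.
#' `write_tvc()` writes the same dialect at full double precision, so a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param path file path.
#' @param ... passed on to [tvc_data()] (e.g. `x_cols`, `z_cols`).
#' @return `read_tvc()` returns a [tvc_data()] object; `write_tvc()`
#'   returns `path` invisibly.
#' @export
read_tvc <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if ("yR" %in% names(df)) {
    df$yR <- suppressWarnings(as.numeric(df$yR))
    df$yR[is.na(df$yR)] <- Inf
  }
  tvc_data(df, ...)
}

#' @param data a [tvc_data()] object (or long-format data frame).
#' @param header_lines optional character vector written as `#`-prefixed
#'   comment lines before the header (used by the CLI to record seeds).
#' @rdname read_tvc
#' @export
write_tvc <- function(data, path, header_lines = NULL) {
  df <- if (inherits(data, "tvc_data")) as.data.frame(data) else as.data.frame(data)
  fmt <- function(v) {
    if (!is.numeric(v)) return(as.character(v))
    out <- sprintf("%.17g", v)
    out[is.infinite(v) & v > 0] <- "Inf"
    out
  }
  cols <- lapply(df, fmt)
  lines <- c(
    if (length(header_lines)) paste0("# ", header_lines),
    paste(names(df), collapse = ","),
    do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}
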