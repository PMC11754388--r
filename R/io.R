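## Text round-tripping of panel datasets, draws and reports. Numeric columns
## are written with 17 significant digits so floats survive bitwise.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a panel dataset as long-format delimited text
#'
#' One row per (individual, occasion): columns `id`, `t`, `eta_y` (or
#' `y_1..y_K`), optional `eta_z`, optional `state`, and the per-individual
#' between-level covariates `x_1..x_Q` repeated across rows. A sidecar JSON
#' (`<path>.json`) records dimensions and, for simulated data, the generating
#' truth.
#'
#' @param data an `"msar_panel"` (or simulated) dataset.
#' @param path output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  stopifnot(inherits(data, "msar_panel"))
  N <- data$N; Tn <- data$T; K <- data$K; Q <- data$Q
  id <- rep(seq_len(N), each = Tn)
  tt <- rep(seq_len(Tn), N)
  df <- data.frame(id = id, t = tt)
  for (k in seq_len(K)) {
    df[[if (K == 1) "eta_y" else paste0("y_", k)]] <-
      fmt17(as.vector(t(data$eta_y[, , k])))
  }
  if (!is.null(data$eta_z)) df$eta_z <- fmt17(as.vector(t(data$eta_z)))
  if (!is.null(data$states)) df$state <- as.vector(t(data$states))
  for (q in seq_len(Q)) {
    df[[paste0("x_", q)]] <- fmt17(rep(data$eta_x[, q], each = Tn))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(N = N, T = Tn, K = K, Q = Q,
               has_eta_z = !is.null(data$eta_z),
               has_states = !is.null(data$states),
               latent_columns = "all columns hold latent-scale values (unit loadings, zero measurement error)")
  if (!is.null(data$true_beta_star)) side$true_beta_star <- data$true_beta_star
  if (!is.null(data$true_eps0)) side$true_eps0 <- data$true_eps0
  if (!is.null(data$design)) {
    side$design <- unclass(data$design)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a panel dataset written by [write_panel()]
#'
#' @param path the data file; the sidecar JSON `<path>.json` must exist.
#' @return An `"msar_panel"` (with truth fields restored when present).
#' @export
read_panel <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character"),
    error = function(e) stop("read_panel: parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("id", "t", if (side$K == 1) "eta_y" else paste0("y_", seq_len(side$K)),
            paste0("x_", seq_len(side$Q)))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_panel: missing column(s) ", paste(miss, collapse = ", "),
         " in '", path, "'", call. = FALSE)
  }
  N <- side$N; Tn <- side$T; K <- side$K; Q <- side$Q
  ord <- order(as.integer(df$id), as.integer(df$t))
  df <- df[ord, ]
  eta_y <- array(NA_real_, c(N, Tn, K))
  for (k in seq_len(K)) {
    col <- if (K == 1) "eta_y" else paste0("y_", k)
    eta_y[, , k] <- matrix(as.numeric(df[[col]]), N, Tn, byrow = TRUE)
  }
  eta_x <- sapply(seq_len(Q), function(q) {
    matrix(as.numeric(df[[paste0("x_", q)]]), N, Tn, byrow = TRUE)[, 1]
  })
  eta_x <- matrix(eta_x, N, Q)
  eta_z <- if (isTRUE(side$has_eta_z)) {
    matrix(as.numeric(df$eta_z), N, Tn, byrow = TRUE)
  }
  states <- if (isTRUE(side$has_states)) {
    matrix(as.integer(df$state), N, Tn, byrow = TRUE)
  }
  out <- panel_dataset(eta_y, eta_x, eta_z = eta_z, states = states)
  if (!is.null(side$true_beta_star)) out$true_beta_star <- side$true_beta_star
  if (!is.null(side$true_eps0)) out$true_eps0 <- side$true_eps0
  if (!is.null(side$design)) {
    d <- side$design
    out$design <- structure(d, class = "msar_design")
    class(out) <- c("msar_sim", class(out))
  }
  out
}

#' Write posterior draws as delimited text
#'
#' Long format with columns `chain`, `draw`, `parameter`, `value`.
#'
#' @param fit an `"msar_fit"`.
#' @param path output file.
#' @param pars subset of parameter names (default: all monitored).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path, pars = NULL) {
  arr <- fit$draws
  if (is.null(pars)) pars <- dimnames(arr)[[3]]
  keep <- dim(arr)[1]; ch <- dim(arr)[2]
  rows <- expand.grid(draw = seq_len(keep), chain = seq_len(ch))
  out <- do.call(rbind, lapply(pars, function(p) {
    data.frame(chain = rows$chain, draw = rows$draw, parameter = p,
               value = fmt17(as.vector(arr[, , p])))
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a filter result as delimited text
#'
#' @param fr an `"msar_filter"` from [forward_loglik()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter <- function(fr, path) {
  stopifnot(inherits(fr, "msar_filter"))
  N <- dim(fr$xi)[1]; Tn <- dim(fr$xi)[2]
  df <- data.frame(id = rep(seq_len(N), each = Tn), t = rep(seq_len(Tn), N),
                   xi1 = fmt17(as.vector(t(fr$xi[, , 1]))),
                   xi2 = fmt17(as.vector(t(fr$xi[, , 2]))),
                   loglik_t = fmt17(as.vector(t(fr$per_time_loglik))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
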