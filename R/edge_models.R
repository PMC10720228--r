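# Per-connection linear models: Fisher-z FC ~ group + sex + age_std +
# mean_fd + intercept, with two-sided group p-values and partial eta^2.

#' Build the per-edge design matrix from a subject manifest
#'
#' Columns `[intercept, group, sex, age_std, mean_fd]`. Group and sex are
#' dummy-coded 0/1 against their first factor level (reference recorded in
#' the `coding` attribute); age is standardized to mean 0, sample
#' (n-1) standard deviation 1 over the included subjects. Set
#' `covariates = FALSE` for the group-only design, under which the edge
#' model reduces to a two-sample t-test.
#'
#' @param manifest Data frame with columns `group`, `sex`, `age`, `mean_fd`.
#' @param covariates Include sex, standardized age and mean FD? Default TRUE.
#' @return Numeric design matrix with a `coding` attribute.
#' @export
build_design <- function(manifest, covariates = TRUE) {
  group <- factor(manifest$group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  if (min(table(group)) < 2) stop("need at least 2 subjects per group")
  x <- cbind(intercept = 1, group = as.numeric(group == levels(group)[2]))
  coding <- list(group_reference = levels(group)[1])
  if (covariates) {
    sex <- factor(manifest$sex)
    if (nlevels(sex) != 2) stop("sex must have exactly 2 levels")
    if (stats::sd(manifest$age) == 0) stop("age has zero variance")
    x <- cbind(x,
               sex = as.numeric(sex == levels(sex)[2]),
               age_std = as.numeric(scale(manifest$age)),
               mean_fd = manifest$mean_fd)
    coding$sex_reference <- levels(sex)[1]
  }
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  attr(x, "coding") <- coding
  x
}

# Shared OLS machinery: one QR of the design, solved for a matrix of edge
# responses at once.
edge_ols <- function(z, design) {
  z <- as.matrix(z)
  n <- nrow(design); k <- ncol(design); df <- n - k
  if (df < 1) stop("not enough subjects for the residual degrees of freedom")
  qr_x <- qr(design)
  if (qr_x$rank < k) stop("singular design matrix")
  coefs <- qr.coef(qr_x, z)
  resid <- qr.resid(qr_x, z)
  sigma2 <- colSums(resid^2) / df
  xtx_inv_gg <- chol2inv(qr.R(qr_x))[match("group", colnames(design)),
                                     match("group", colnames(design))]
  beta <- coefs["group", ]
  se <- sqrt(sigma2 * xtx_inv_gg)
  t_stat <- ifelse(se > 0, beta / se, NA_real_)
  list(beta = beta, t = t_stat,
       p = 2 * stats::pt(-abs(t_stat), df),
       partial_eta2 = t_stat^2 / (t_stat^2 + df), df = df)
}

#' Fit the group model at a single connection
#'
#' Ordinary least squares of per-subject Fisher-z values on the design; the
#' group effect is tested two-sided with `df = n - ncol(design)` and
#' summarized by partial eta^2 `= t^2 / (t^2 + df)` and the unadjusted
#' case-minus-control mean z difference.
#'
#' @param z Per-subject Fisher-z values at one edge.
#' @param design Design matrix from [build_design()].
#' @param group Optional group factor (taken from the design's 0/1 group
#'   column when omitted) used for the raw mean difference.
#' @return One-row data frame: `beta_group`, `t_group`, `p_group`,
#'   `partial_eta2`, `group_mean_diff_z`, `df`.
#' @export
fit_edge <- function(z, design, group = NULL) {
  stopifnot(length(z) == nrow(design))
  fit <- edge_ols(cbind(z), design)
  g <- if (is.null(group)) design[, "group"] else as.numeric(factor(group)) - 1
  data.frame(beta_group = unname(fit$beta), t_group = unname(fit$t),
             p_group = unname(fit$p),
             partial_eta2 = unname(fit$partial_eta2),
             group_mean_diff_z = mean(z[g == 1]) - mean(z[g == 0]),
             df = fit$df)
}

#' Fit the group model at every connection
#'
#' One linear model per edge, solved jointly through a single QR
#' decomposition of the shared design. Edges with degenerate data (zero
#' residual variance or missing values) are flagged, not dropped, so the
#' p-value set stays aligned with the canonical edge ordering.
#'
#' @param z_matrix n_subjects x n_edges matrix of Fisher-z values, columns
#'   in canonical edge order.
#' @param design Design matrix from [build_design()].
#' @param edge_index Optional data frame `i`, `j` labelling the edges.
#' @return Data frame of class `edge_table`: one row per edge with the
#'   [fit_edge()] statistics plus a logical `flagged` column.
#' @export
fit_all_edges <- function(z_matrix, design, edge_index = NULL) {
  z_matrix <- as.matrix(z_matrix)
  stopifnot(nrow(z_matrix) == nrow(design))
  fit <- edge_ols(z_matrix, design)
  g <- design[, "group"]
  diff_z <- colMeans(z_matrix[g == 1, , drop = FALSE]) -
    colMeans(z_matrix[g == 0, , drop = FALSE])
  centered <- z_matrix - rep(colMeans(z_matrix), each = nrow(z_matrix))
  degenerate <- colSums(centered^2) <= 1e-20
  flagged <- !is.finite(fit$t) | !is.finite(fit$p) | degenerate
  out <- data.frame(beta_group = fit$beta, t_group = fit$t,
                    p_group = fit$p, partial_eta2 = fit$partial_eta2,
                    group_mean_diff_z = diff_z, df = fit$df,
                    flagged = flagged)
  if (!is.null(edge_index)) out <- cbind(edge_index[c("i", "j")], out)
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}

# Stack per-subject Fisher-z connectivity matrices into the
# n_subjects x n_edges matrix that fit_all_edges() consumes.
stack_edges <- function(fc_matrices, idx = NULL) {
  p <- nrow(fc_matrices[[1]])
  if (is.null(idx)) idx <- edge_index_table(p)
  vals <- vapply(fc_matrices, vectorize_edges, numeric(nrow(idx)), idx = idx)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)   # single edge
  t(vals)
}
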