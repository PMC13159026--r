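# Evaluation metrics and downstream group statistics.

#' Dice similarity coefficient
#'
#' `DSC(X, Y) = 2 |X n Y| / (|X| + |Y|)`: overlap of two binary masks, 1
#' for identical non-empty masks, 0 for disjoint ones.
#'
#' @param X,Y Binary arrays of identical shape.
#' @return Dimensionless DSC.
#' @export
dice <- function(X, Y) {
  stopifnot(all(dim(X) == dim(Y)))
  x <- X >= 0.5; y <- Y >= 0.5
  denom <- sum(x) + sum(y)
  if (denom == 0) stop("both masks are empty; DSC undefined")
  2 * sum(x & y) / denom
}

# boundary voxels: mask voxels with at least one face-neighbor outside the
# mask (the outside of the grid counts as background); works for 2D and 3D
mask_boundary <- function(X) {
  X <- X >= 0.5
  d <- dim(X)
  nd <- length(d)
  if (nd == 2) dim(X) <- d <- c(d, 1L)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- X
  sub <- function(i, j, k) pad[i, j, k, drop = FALSE]
  inner <- sub(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
  all_nb <- sub(1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)) &
            sub(3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)) &
            sub(2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)) &
            sub(2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1))
  if (d[3] > 1) {
    all_nb <- all_nb & sub(2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]) &
                       sub(2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2))
  }
  which(inner & !all_nb, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Robust variant of the Hausdorff boundary distance: directed
#' boundary-to-boundary distances are computed in both directions (in mm,
#' via the voxel spacing) and the 95th percentile of the pooled collection
#' is returned instead of the supremum.
#'
#' @param X,Y Binary arrays of identical shape, both non-empty.
#' @param spacing Voxel spacing per axis (mm); recycled to the array
#'   dimensionality.
#' @param percentile Percentile of the pooled directed distances.
#' @return Distance in mm (0 for identical masks).
#' @export
hausdorff95 <- function(X, Y, spacing = 1, percentile = 95) {
  stopifnot(all(dim(X) == dim(Y)))
  if (!any(X >= 0.5) || !any(Y >= 0.5)) stop("hausdorff95 needs non-empty masks")
  nd <- length(dim(X))
  spacing <- rep_len(spacing, max(nd, 3))
  bx <- sweep(mask_boundary(X), 2, spacing[seq_len(3)], `*`)
  by <- sweep(mask_boundary(Y), 2, spacing[seq_len(3)], `*`)
  # all-pairs distances; boundary sets are small relative to the volumes
  d2 <- outer(rowSums(bx^2), rowSums(by^2), `+`) - 2 * bx %*% t(by)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  directed <- c(apply(d, 1, min), apply(d, 2, min))
  as.numeric(stats::quantile(directed, percentile / 100, type = 7))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, capped at 1 and
#' order-preserving.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Per-position group models for thickness profiles
#'
#' Ordinary least squares per response column (thickness position) with a
#' group indicator and the covariates age, sex, and total brain volume;
#' two-sided p-values for the group coefficient; Benjamini-Hochberg
#' q-values across positions.  Patients are coded 1, so a negative beta is
#' a reduction in patients.  Subjects with a missing response at a position
#' are excluded listwise for that position.
#'
#' @param design Data frame with columns `group` (0/1), `age`, `sex`
#'   (0/1), `brain_volume`.
#' @param responses Numeric matrix, subjects x positions.
#' @return Data frame with `position`, `beta`, `p`, `q`.
#' @export
fit_group_models <- function(design, responses) {
  responses <- as.matrix(responses)
  stopifnot(nrow(design) == nrow(responses))
  req <- c("group", "age", "sex", "brain_volume")
  if (!all(req %in% names(design)))
    stop("design needs columns: ", paste(req, collapse = ", "))
  if (anyNA(design[req])) stop("missing covariates in design")
  if (length(unique(design$group)) < 2 || min(table(design$group)) < 2)
    stop("need at least 2 subjects per group")
  Xfull <- cbind(1, design$group, design$age, design$sex, design$brain_volume)
  colnames(Xfull) <- c("(Intercept)", "group", "age", "sex", "brain_volume")
  # drop constant covariate columns (keep intercept and group)
  keep <- c(TRUE, TRUE, apply(Xfull[, -(1:2), drop = FALSE], 2,
                              function(x) stats::sd(x) > 0))
  X <- Xfull[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")

  npos <- ncol(responses)
  beta <- p <- rep(NA_real_, npos)
  complete <- !apply(responses, 2, anyNA)
  fit_cols <- function(Xs, Ys) {
    qrx <- qr(Xs)
    coef <- qr.coef(qrx, Ys)
    res <- Ys - Xs %*% coef
    df <- nrow(Xs) - ncol(Xs)
    sigma2 <- colSums(res^2) / df
    XtXinv <- chol2inv(qr.R(qrx))
    se <- sqrt(XtXinv[2, 2] * sigma2)
    tval <- coef[2, ] / se
    list(beta = coef[2, ], p = 2 * stats::pt(-abs(tval), df))
  }
  if (any(complete)) {
    f <- fit_cols(X, responses[, complete, drop = FALSE])
    beta[complete] <- f$beta
    p[complete] <- f$p
  }
  for (j in which(!complete)) {
    ok <- !is.na(responses[, j])
    if (sum(ok) <= ncol(X)) next
    f <- fit_cols(X[ok, , drop = FALSE], responses[ok, j, drop = FALSE])
    beta[j] <- f$beta
    p[j] <- f$p
  }
  q <- rep(NA_real_, npos)
  q[!is.na(p)] <- benjamini_hochberg(p[!is.na(p)])
  data.frame(position = seq_len(npos), beta = beta, p = p, q = q)
}

#' Intraclass correlation for absolute agreement
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC
#' (ICC(2,1)): variance decomposition over subjects and measurement
#' occasions, penalizing systematic offsets between occasions (equality,
#' not mere correlation).
#'
#' @param measurements n x k matrix (k = 2 for test-retest).
#' @param type `"agreement"` (default) or `"consistency"` (ICC(3,1)).
#' @return ICC value.
#' @export
icc_absolute <- function(measurements, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  M <- as.matrix(measurements)
  n <- nrow(M); k <- ncol(M)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 measurements")
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot < .Machine$double.eps) stop("zero total variance; ICC undefined")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}
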