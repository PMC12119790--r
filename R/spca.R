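#' ON-OFF difference matrix for one task
#'
#' Pairs ON and OFF rows sharing `(patient_id, visit_id)` within a task and
#' forms the per-feature difference ON value minus OFF value.  Unmatched
#' rows are dropped (count reported via a message), as are paired rows with
#' any missing feature.  When a (patient, visit, condition) cell holds
#' several recordings they are averaged first.
#'
#' @param table Feature table.
#' @param task Task label.
#' @param features Feature columns (default: canonical features present).
#' @return Numeric matrix (rows = patient-visit pairs, named
#'   `patient.visit`; columns = features) with attribute `task`.
#' @export
compute_differences <- function(table, task, features = NULL) {
  if (is.null(features)) {
    features <- intersect(kinematic_features("core"), names(table))
  }
  tab <- table[table$task == task, , drop = FALSE]
  if (!nrow(tab)) {
    stop_kinemed(sprintf("no rows for task `%s`", task),
                 "kinemed_validation_error")
  }
  key <- interaction(tab$patient_id, tab$visit_id, drop = TRUE)
  split_rows <- split(seq_len(nrow(tab)), key)
  rows <- list()
  dropped <- 0L
  for (k in names(split_rows)) {
    idx <- split_rows[[k]]
    on <- idx[tab$condition[idx] == "ON"]
    off <- idx[tab$condition[idx] == "OFF"]
    if (!length(on) || !length(off)) {
      dropped <- dropped + length(idx)
      next
    }
    on_v <- colMeans(tab[on, features, drop = FALSE])
    off_v <- colMeans(tab[off, features, drop = FALSE])
    rows[[k]] <- on_v - off_v
  }
  if (dropped > 0) {
    message(sprintf("compute_differences: %d unmatched recording(s) dropped",
                    dropped))
  }
  m <- do.call(rbind, rows)
  if (is.null(m) || !nrow(m)) {
    stop_kinemed("no complete ON/OFF pairs", "kinemed_validation_error")
  }
  ok <- complete.cases(m)
  if (any(!ok)) {
    message(sprintf("compute_differences: %d pair(s) with missing features dropped",
                    sum(!ok)))
    m <- m[ok, , drop = FALSE]
  }
  attr(m, "task") <- task
  m
}

#' Standardize a difference matrix
#'
#' Centres and scales each column to zero mean, unit variance.  Columns
#' with zero variance are dropped with a warning.
#'
#' @param x Numeric matrix.
#' @return Standardized matrix (attributes `center`, `scale`, `dropped`).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2, sd)
  zero <- !is.finite(s) | s < .Machine$double.eps^0.5
  if (any(zero)) {
    warning("zero-variance column(s) dropped: ",
            paste(colnames(x)[zero], collapse = ", "))
  }
  keep <- !zero
  out <- scale(x[, keep, drop = FALSE])
  res <- out[, , drop = FALSE]
  attr(res, "center") <- attr(out, "scaled:center")
  attr(res, "scale") <- attr(out, "scaled:scale")
  attr(res, "dropped") <- colnames(x)[zero]
  attr(res, "task") <- attr(x, "task")
  res
}

#' Sparse principal component analysis
#'
#' Solves the reconstruction-plus-L1 form of sparse PCA,
#' \deqn{\min_{U,V} \tfrac12 \|X - U V\|_F^2 + \alpha \|V\|_1
#'       \quad \text{s.t.} \quad \|u_j\|_2 \le 1,}
#' where the rows of `V` are the sparse component loadings.  The solver is
#' deterministic (repeated fits are identical) and proceeds in three
#' stages chosen to avoid the two failure modes of cold-started
#' block-coordinate solvers on correlated data — splitting one latent
#' dimension across several components, and spurious cross-loadings that
#' survive because no other component explains them away:
#'
#' 1. The dimension of the signal subspace `r` is estimated by counting
#'    eigenvalues above the Marchenko-Pastur bulk edge
#'    `(1 + sqrt(p/n))^2` (scaled by the mean column variance), and the
#'    top-`r` principal axes are varimax-rotated so the starting basis is
#'    already unmixed.  Each rotated direction is refined by alternating
#'    an exact least-squares update of its score vector with a
#'    soft-thresholding update of its loadings, and deflated.
#' 2. The `r` leading components are then polished jointly by
#'    block-coordinate sweeps of the same objective, which lets each
#'    component explain away the features it owns and prunes the other
#'    components' spurious loadings on them.
#' 3. Any further components up to `n_components` are extracted greedily
#'    from the remaining residual (leading singular vector init, same
#'    rank-one updates); they summarise what is left and populate the
#'    tail of the variance curve, but are excluded from the polish so
#'    they cannot raid a weak signal dimension.
#'
#' The L1 penalty forces exact zero loadings, yielding components defined
#' by small subsets of features.  Component signs are normalised so each
#' component's largest-magnitude loading is positive.
#'
#' Explained variance uses the adjusted-variance convention for
#' non-orthogonal components: the data are projected onto the unit-norm
#' loading directions, the projection basis is orthogonalised sequentially
#' (QR), variance is attributed in component order and divided by the total
#' variance of the input matrix; components are ordered by decreasing
#' adjusted variance.
#'
#' @param x Standardized data matrix (samples x features).
#' @param n_components Number of components to extract.
#' @param l1_penalty Non-negative L1 penalty `alpha` (default 1, the
#'   conventional setting on standardized difference scores).
#' @param max_iter,tol Optimisation controls.
#' @return Object of class `sparse_pca`: `loadings` (features x components),
#'   `scores`, `ev_fraction` (adjusted explained-variance fractions,
#'   non-increasing), `cum_var`, `penalty`, `iterations`, `converged`.
#'   Components whose loadings are penalised to all-zero are dropped with a
#'   warning.
#' @references Zou, Hastie & Tibshirani (2006) Sparse principal component
#'   analysis, JCGS 15(2); Mairal et al. (2010) Online learning for matrix
#'   factorization and sparse coding, JMLR 11.
#' @export
fit_sparse_pca <- function(x, n_components, l1_penalty = 1,
                           max_iter = 500, tol = 1e-7) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  k <- as.integer(n_components)
  stopifnot(k >= 1, k <= min(n, p))
  check_number(l1_penalty, "l1_penalty", lower = 0)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))

  U <- matrix(0, n, k)
  V <- matrix(0, k, p)
  E <- x
  converged <- TRUE
  it <- 0L

  # rank-one refinement of one component on the residual E
  refine <- function(E, vj) {
    uj <- NULL
    for (iter in seq_len(max_iter)) {
      v_old <- vj
      Ev <- drop(E %*% vj)
      nEv <- sqrt(sum(Ev^2))
      if (nEv == 0) return(list(u = NULL, iter = iter))
      uj <- Ev / nEv
      z <- drop(crossprod(E, uj))
      vj <- sign(z) * pmax(abs(z) - l1_penalty, 0)
      if (all(vj == 0)) return(list(u = NULL, iter = iter))
      if (max(abs(vj - v_old)) < tol * max(1, max(abs(v_old)))) {
        return(list(u = uj, v = vj, iter = iter, conv = TRUE))
      }
    }
    list(u = uj, v = vj, iter = max_iter, conv = FALSE)
  }

  # stage 1: signal-subspace estimate, varimax-unmixed starts
  sv <- svd(x, nu = 0, nv = min(k, p))
  lam <- sv$d^2 / (n - 1)
  mp_edge <- mean(apply(x, 2, var)) * (1 + sqrt(p / n))^2
  r <- max(1L, min(k, sum(lam > mp_edge)))
  V0 <- sv$v[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  if (r >= 2) {
    V0 <- stats::varimax(V0, normalize = FALSE)$loadings[, , drop = FALSE]
    V0 <- V0[, order(-colSums(V0^2)), drop = FALSE]
  }
  for (j in seq_len(r)) {
    s <- sign(V0[which.max(abs(V0[, j])), j])
    if (s < 0) V0[, j] <- -V0[, j]
  }

  for (j in seq_len(k)) {
    init <- if (j <= r) {
      V0[, j]
    } else {
      se <- svd(E, nu = 0, nv = 1)
      vv <- se$v[, 1] * se$d[1]
      if (vv[which.max(abs(vv))] < 0) vv <- -vv
      vv
    }
    res <- refine(E, init)
    it <- it + res$iter
    if (is.null(res$u)) next            # all-zero component; dropped below
    if (!isTRUE(res$conv)) converged <- FALSE
    U[, j] <- res$u
    V[j, ] <- res$v
    E <- E - res$u %*% t(res$v)
  }

  # stage 2: joint polish of the r leading components (explaining-away
  # prunes spurious cross-loadings; tail components stay frozen)
  if (r >= 2) {
    for (sweep_i in seq_len(max_iter)) {
      V_old <- V
      for (j in seq_len(r)) {
        if (all(V[j, ] == 0)) next
        Rj <- E + U[, j, drop = FALSE] %*% V[j, , drop = FALSE]
        vj <- V[j, ]
        Rv <- drop(Rj %*% vj)
        nRv <- sqrt(sum(Rv^2))
        if (nRv == 0) next
        uj <- Rv / nRv
        z <- drop(crossprod(Rj, uj))
        vj <- sign(z) * pmax(abs(z) - l1_penalty, 0)
        U[, j] <- uj
        V[j, ] <- vj
        E <- Rj - U[, j, drop = FALSE] %*% V[j, , drop = FALSE]
      }
      it <- it + 1L
      if (max(abs(V - V_old)) < tol * max(1, max(abs(V_old)))) break
      if (sweep_i == max_iter) converged <- FALSE
    }
  }

  # sign normalisation: largest-|loading| entry positive
  for (j in seq_len(k)) {
    nz <- which(abs(V[j, ]) > 0)
    if (length(nz)) {
      s <- sign(V[j, nz[which.max(abs(V[j, nz]))]])
      if (s < 0) { V[j, ] <- -V[j, ]; U[, j] <- -U[, j] }
    }
  }

  zero_comp <- apply(V, 1, function(v) all(v == 0))
  if (any(zero_comp)) {
    warning(sprintf("%d component(s) penalised to all-zero loadings dropped",
                    sum(zero_comp)))
    V <- V[!zero_comp, , drop = FALSE]
    U <- U[, !zero_comp, drop = FALSE]
    k <- nrow(V)
    if (k == 0L) {
      stop_kinemed("penalty too large: every component is all-zero",
                   "kinemed_validation_error")
    }
  }

  total_var <- sum(apply(x, 2, var))
  adj <- function(ord) {
    W <- V[ord, , drop = FALSE]
    W <- W / sqrt(rowSums(W^2))
    S <- x %*% t(W)
    S <- sweep(S, 2, colMeans(S))   # variance, not raw sum of squares
    R <- qr.R(qr(S))
    diag(R)^2 / ((n - 1) * total_var)
  }
  ev0 <- adj(seq_len(k))
  ord <- order(ev0, decreasing = TRUE)
  ev <- adj(ord)
  if (is.unsorted(rev(ev))) {          # re-sort once if attribution reordered
    ord <- ord[order(ev, decreasing = TRUE)]
    ev <- adj(ord)
  }
  V <- V[ord, , drop = FALSE]
  U <- U[, ord, drop = FALSE]

  loadings <- t(V)
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(
    list(loadings = loadings,
         scores = U,
         ev_fraction = as.numeric(ev),
         cum_var = cumsum(as.numeric(ev)),
         penalty = l1_penalty,
         n = n,
         iterations = it,
         converged = converged),
    class = "sparse_pca"
  )
}

#' @export
print.sparse_pca <- function(x, digits = 3, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("<sparse_pca> %d components, penalty %g, n = %d%s\n",
              k, x$penalty, x$n,
              if (!x$converged) " (max iterations reached)" else ""))
  nz <- colSums(x$loadings != 0)
  cat("  nonzero loadings:", paste(nz, collapse = ", "), "\n")
  cat("  adjusted EV fractions:",
      paste(signif(x$ev_fraction, digits), collapse = ", "), "\n")
  cat("  cumulative:", paste(signif(x$cum_var, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.sparse_pca <- function(x, ...) {
  plot(seq_along(x$cum_var), x$cum_var, type = "b",
       xlab = "components", ylab = "cumulative adjusted variance",
       ylim = c(0, 1), ...)
  invisible(x)
}

#' Choose the number of components from the cumulative variance curve
#'
#' Default method: the elbow at the maximum second difference of the
#' cumulative curve, i.e. the component after which the per-component
#' variance increment drops the most.  If no drop exceeds `min_drop` the
#' elbow is considered undefined and the configured minimum is returned
#' with a warning.  An explicit `override` wins regardless of the curve.
#'
#' @param cum_var Non-decreasing cumulative explained-variance vector (or a
#'   `sparse_pca` object).
#' @param method Only `"elbow"` is implemented.
#' @param override Explicit component count.
#' @param min_components Fallback when the elbow is undefined.
#' @param min_drop Smallest increment drop treated as a real elbow.
#' @return Integer component count.
#' @export
select_n_components <- function(cum_var, method = "elbow", override = NULL,
                                min_components = 1L, min_drop = 0.05) {
  if (inherits(cum_var, "sparse_pca")) cum_var <- cum_var$cum_var
  if (!is.null(override)) return(as.integer(override))
  method <- match.arg(method, "elbow")
  inc <- diff(c(0, cum_var))
  if (length(inc) < 2L) return(max(1L, min_components))
  drops <- inc[-length(inc)] - inc[-1]
  if (max(drops) < min_drop) {
    warning("elbow undefined (near-linear cumulative variance curve); ",
            "returning the configured minimum")
    return(as.integer(min_components))
  }
  as.integer(which.max(drops))
}

#' Cross-task stability of one component's loadings
#'
#' Pearson correlation between the loading vectors of rank-matched
#' components from two tasks, computed over all features except those with
#' an exactly zero loading in *both* tasks (the jointly-zero features are
#' reported).  Two-sided p-value from the usual t approximation on the
#' number of compared features (small-n caveat applies).
#'
#' @param model_a,model_b `sparse_pca` fits over the same feature canon.
#' @param component Component index (rank order, as in cross-task
#'   comparisons of corresponding components).
#' @return Object of class `stability_result`: `component`, `r`, `p_value`,
#'   `n_features`, `excluded`.
#' @export
loading_stability <- function(model_a, model_b, component = 1L) {
  stopifnot(inherits(model_a, "sparse_pca"), inherits(model_b, "sparse_pca"))
  fa <- rownames(model_a$loadings)
  fb <- rownames(model_b$loadings)
  if (!identical(fa, fb)) {
    stop_kinemed("models were fitted over different feature canons",
                 "kinemed_validation_error")
  }
  stopifnot(component >= 1,
            component <= ncol(model_a$loadings),
            component <= ncol(model_b$loadings))
  va <- model_a$loadings[, component]
  vb <- model_b$loadings[, component]
  joint_zero <- va == 0 & vb == 0
  keep <- !joint_zero
  n <- sum(keep)
  if (n < 3) {
    warning("fewer than 3 jointly nonzero features; correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else if (sd(va[keep]) == 0 || sd(vb[keep]) == 0) {
    warning("degenerate loading vector (zero variance over compared features)")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(va[keep], vb[keep], alternative = "two.sided")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(component = as.integer(component), r = r, p_value = p,
                 n_features = n, excluded = fa[joint_zero]),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> PC%d: r = %.3f, p = %.3g (n = %d features; %d jointly zero excluded)\n",
              x$component, x$r, x$p_value, x$n_features, length(x$excluded)))
  invisible(x)
}

#' Top-loading features of a component
#'
#' Features ranked by absolute loading (ties broken by canonical feature
#' order); zero loadings are never returned, so fewer than `k` rows may
#' come back.  The result is radar-plot-ready.
#'
#' @param model A `sparse_pca` fit.
#' @param component Component index.
#' @param k Number of features to report (default 4).
#' @return Data frame with `feature`, `loading`, `rank`.
#' @export
top_loadings <- function(model, component = 1L, k = 4L) {
  stopifnot(inherits(model, "sparse_pca"),
            component >= 1, component <= ncol(model$loadings))
  v <- model$loadings[, component]
  nz <- which(v != 0)
  if (!length(nz)) {
    warning("component has no nonzero loadings")
    return(data.frame(feature = character(0), loading = numeric(0),
                      rank = integer(0)))
  }
  ord <- nz[order(-abs(v[nz]), nz)]
  ord <- head(ord, k)
  data.frame(feature = names(v)[ord], loading = unname(v[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
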