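#' Group structure over bit columns
#'
#' Partitions the bit columns of an encoded matrix into named, contiguous,
#' mutually exclusive groups (one per alignment file/locus). The default
#' group weight is sqrt(group size), the usual sparse-group-LASSO choice
#' that puts groups of different sizes on a comparable penalty scale.
#'
#' @param feature_map Feature map of an encoded matrix (columns grouped
#'   contiguously by `group`).
#' @param weights Optional named numeric vector overriding weights for some
#'   or all groups (e.g. from [read_group_weights()]).
#' @return An `esl_groups` data.frame with `name`, half-open 0-based column
#'   range `start`/`end`, and `weight`.
#' @export
group_structure <- function(feature_map, weights = NULL) {
  r <- rle(feature_map$group)
  ends <- cumsum(r$lengths)
  g <- data.frame(name = r$values,
                  start = c(0L, ends[-length(ends)]),
                  end = ends,
                  weight = sqrt(r$lengths),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$name)) {
    stop("bit columns of a group must be contiguous in the feature map",
         call. = FALSE)
  }
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), g$name)
    if (length(unknown)) {
      stop("group weights given for unknown group(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    hit <- match(g$name, names(weights))
    g$weight[!is.na(hit)] <- weights[hit[!is.na(hit)]]
  }
  if (any(g$weight < 0)) stop("group weights must be >= 0", call. = FALSE)
  class(g) <- c("esl_groups", "data.frame")
  g
}

#' Read a group-weights file
#'
#' Two tab-separated columns: group name, then its penalty weight.
#'
#' @param path Path to the file.
#' @return Named numeric vector of weights.
#' @export
read_group_weights <- function(path) {
  if (!file.exists(path)) stop("group weight file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("group", "weight"))
  if (anyDuplicated(tab$group)) stop("duplicate group in ", path,
                                     call. = FALSE)
  if (!is.numeric(tab$weight) || anyNA(tab$weight)) {
    stop("non-numeric group weight in ", path, call. = FALSE)
  }
  stats::setNames(tab$weight, tab$group)
}

# numerically safe log(1 + exp(x))
.log1pexp <- function(x) {
  out <- x
  lo <- x <= 33
  out[lo] <- log1p(exp(pmin(x[lo], 33)))
  out
}

#' Weighted logistic loss
#'
#' `(1 / sum(w)) * sum_i w_i log(1 + exp(-y_i (x_i beta + intercept)))`.
#' Normalizing by total weight keeps the penalty scale comparable across
#' dataset sizes.
#'
#' @param beta Coefficient vector over bit columns.
#' @param intercept Unpenalized intercept.
#' @param X Design matrix (rows = taxa).
#' @param y Labels in -1/+1.
#' @param w Positive sample weights (default 1).
#' @return Nonnegative scalar.
#' @export
logistic_loss <- function(beta, intercept, X, y, w = rep(1, length(y))) {
  stopifnot(length(y) == nrow(X), length(beta) == ncol(X), all(w > 0))
  m <- y * (as.numeric(X %*% beta) + intercept)
  sum(w * .log1pexp(-m)) / sum(w)
}

# per-group Euclidean norms
.group_norms <- function(beta, groups) {
  vapply(seq_len(nrow(groups)), function(g) {
    idx <- (groups$start[g] + 1L):groups$end[g]
    sqrt(sum(beta[idx]^2))
  }, numeric(1))
}

#' Sparse-group penalty
#'
#' `lambda1 * sum(|beta|) + lambda2 * sum_g w_g ||beta_g||_2` — an L1 term
#' zeroing individual bit columns plus a grouped L2 (not squared) term
#' zeroing whole loci.
#'
#' @param beta Coefficient vector.
#' @param groups An `esl_groups` structure covering `beta`.
#' @param lambda1,lambda2 Penalty strengths (absolute scale).
#' @return Nonnegative scalar.
#' @export
penalty <- function(beta, groups, lambda1, lambda2) {
  lambda1 * sum(abs(beta)) +
    lambda2 * sum(groups$weight * .group_norms(beta, groups))
}

#' Proximal operator of the sparse-group penalty
#'
#' Returns `argmin_u 0.5 ||u - z||^2 + t lambda1 ||u||_1 +
#' t lambda2 sum_g w_g ||u_g||_2`, computed in closed form via the
#' Moreau-Yosida decomposition: elementwise soft-thresholding by
#' `t lambda1`, then per-group block soft-thresholding by
#' `t lambda2 w_g`.
#'
#' @param z Input vector.
#' @param t Step size (> 0).
#' @param lambda1,lambda2 Penalty strengths (absolute scale).
#' @param groups An `esl_groups` structure covering `z`.
#' @return The proximal point (same length as `z`, with exact zeros).
#' @export
prox_sgl <- function(z, t, lambda1, lambda2, groups) {
  stopifnot(t > 0)
  u <- sign(z) * pmax(abs(z) - t * lambda1, 0)
  if (lambda2 > 0) {
    for (g in seq_len(nrow(groups))) {
      idx <- (groups$start[g] + 1L):groups$end[g]
      n2 <- sqrt(sum(u[idx]^2))
      thr <- t * lambda2 * groups$weight[g]
      u[idx] <- if (n2 <= thr) 0 else u[idx] * (1 - thr / n2)
    }
  }
  u
}

#' Smallest L1 penalty with an all-zero solution
#'
#' With beta = 0 and the intercept at its optimum (the weighted log-odds),
#' this is the largest absolute coordinate of the loss gradient; any
#' absolute L1 penalty at or above it leaves beta = 0 optimal (for
#' lambda2 = 0). User-facing lambdas in [0, 1] are multiplied by this value
#' to obtain absolute penalties, making the user scale data-independent.
#'
#' @inheritParams logistic_loss
#' @return Nonnegative scalar.
#' @export
lambda_max <- function(X, y, w = rep(1, length(y))) {
  W <- sum(w)
  wp <- sum(w[y == 1])
  wn <- W - wp
  if (wp == 0 || wn == 0) stop("one class empty", call. = FALSE)
  c0 <- log(wp / wn)
  r <- -y * stats::plogis(-y * c0)          # d loss_i / d eta_i
  g <- as.numeric(Matrix::crossprod(X, w * r)) / W
  max(abs(g), 0)
}

#' Smallest group penalty with an all-zero solution
#'
#' The group-level analogue of [lambda_max()]: with beta = 0 and the
#' intercept at its optimum, the largest weighted group norm of the loss
#' gradient, `max_g ||grad_g||_2 / w_g`. Any absolute group penalty at or
#' above it leaves beta = 0 optimal (for lambda1 = 0). User-facing lambda2
#' values in [0, 1] are multiplied by this value, so each penalty is a
#' fraction of its own critical strength and both user scales span a
#' usable [0, 1] range. Groups with zero weight are unpenalized and are
#' excluded from the maximum.
#'
#' @inheritParams logistic_loss
#' @param groups An `esl_groups` structure.
#' @return Nonnegative scalar.
#' @export
lambda2_max <- function(X, y, w = rep(1, length(y)), groups) {
  W <- sum(w)
  wp <- sum(w[y == 1])
  wn <- W - wp
  if (wp == 0 || wn == 0) stop("one class empty", call. = FALSE)
  c0 <- log(wp / wn)
  r <- -y * stats::plogis(-y * c0)
  g <- as.numeric(Matrix::crossprod(X, w * r)) / W
  ratios <- vapply(seq_len(nrow(groups)), function(k) {
    if (groups$weight[k] <= 0) return(0)
    idx <- (groups$start[k] + 1L):groups$end[k]
    sqrt(sum(g[idx]^2)) / groups$weight[k]
  }, numeric(1))
  max(ratios, 0)
}

#' Solver options
#'
#' @param max_iter Maximum FISTA iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @param no_group_penalty Drop the grouped term (plain L1 logistic LASSO).
#' @return An options list.
#' @export
fit_options <- function(max_iter = 10000L, tol = 1e-6,
                        no_group_penalty = FALSE) {
  stopifnot(max_iter >= 1L, tol > 0)
  list(max_iter = as.integer(max_iter), tol = tol,
       no_group_penalty = isTRUE(no_group_penalty))
}

#' Fit the sparse group LASSO logistic regression
#'
#' Minimizes the weighted logistic loss plus the bi-level sparsity penalty
#' by FISTA with backtracking line search and a monotone fallback: whenever
#' the accelerated step would increase the objective, a plain proximal
#' gradient step from the previous iterate is taken instead and the momentum
#' is restarted, so the objective is non-increasing over accepted iterates.
#' The intercept is unpenalized and updated inside the smooth gradient step.
#' Initialization is deterministic (beta = 0, intercept = weighted
#' log-odds), so fits are reproducible without seeds. User-facing `lambda1`
#' and `lambda2` live on [0, 1]: `lambda1` is scaled by [lambda_max()] and
#' `lambda2` by [lambda2_max()], so each penalty is a fraction of the
#' smallest value that zeroes the whole coefficient vector on its own.
#'
#' @param X Design matrix (taxa x bit columns; dense or `Matrix` sparse).
#' @param y Labels in -1/+1.
#' @param w Positive sample weights (replicates folded in by the caller).
#' @param groups An `esl_groups` partition of the columns.
#' @param lambda1,lambda2 Penalties on [0, 1] (default 0.1 each).
#' @param opts Options from [fit_options()].
#' @param feature_map Optional feature map to attach to the model.
#' @param hypothesis_name Name recorded in the model.
#' @return An `esl_model`: `beta`, `intercept`, user-scale `lambda1`/
#'   `lambda2`, absolute `lambda1_abs`/`lambda2_abs`, `groups`,
#'   `feature_map`, `hypothesis_name`, objective trace `objective`,
#'   `iterations` and `converged`.
#' @export
fit_sgl_logistic <- function(X, y, w = rep(1, length(y)), groups,
                             lambda1 = 0.1, lambda2 = 0.1,
                             opts = fit_options(), feature_map = NULL,
                             hypothesis_name = "hypothesis") {
  p <- ncol(X)
  stopifnot(length(y) == nrow(X), length(w) == length(y))
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1", call. = FALSE)
  if (!any(y == 1) || !any(y == -1)) stop("one class empty", call. = FALSE)
  xvals <- if (inherits(X, "sparseMatrix")) X@x else X
  if (anyNA(xvals) || !all(is.finite(xvals)) || anyNA(y) ||
      anyNA(w) || !all(is.finite(w))) {
    stop("non-finite data", call. = FALSE)
  }
  if (lambda1 < 0 || lambda1 > 1 || lambda2 < 0 || lambda2 > 1) {
    stop("lambda1 and lambda2 must lie in [0, 1]", call. = FALSE)
  }
  if (groups$end[nrow(groups)] != p) {
    stop("group structure does not cover the design matrix", call. = FALSE)
  }
  lmax <- lambda_max(X, y, w)
  l1 <- lambda1 * lmax
  l2 <- if (opts$no_group_penalty) 0 else
    lambda2 * lambda2_max(X, y, w, groups)
  W <- sum(w)
  c0 <- log(sum(w[y == 1]) / sum(w[y == -1]))

  smooth_grad <- function(beta, icept) {
    m <- y * (as.numeric(X %*% beta) + icept)
    r <- w * (-y * stats::plogis(-m))
    list(gb = as.numeric(Matrix::crossprod(X, r)) / W, gc = sum(r) / W)
  }
  fval <- function(beta, icept) logistic_loss(beta, icept, X, y, w)
  objective <- function(beta, icept) {
    fval(beta, icept) + penalty(beta, groups, l1, l2)
  }

  beta <- numeric(p)
  icept <- c0
  yb <- beta; yc <- icept
  tk <- 1
  L <- 1
  Fcur <- objective(beta, icept)
  trace <- Fcur
  converged <- FALSE
  iter <- 0L

  # backtracking proximal step from (b0, c0v); returns accepted point and L
  prox_step <- function(b0, c0v, L) {
    gr <- smooth_grad(b0, c0v)
    f0 <- fval(b0, c0v)
    repeat {
      bn <- prox_sgl(b0 - gr$gb / L, 1 / L, l1, l2, groups)
      cn <- c0v - gr$gc / L
      db <- bn - b0; dc <- cn - c0v
      quad <- f0 + sum(gr$gb * db) + gr$gc * dc +
        (L / 2) * (sum(db^2) + dc^2)
      if (fval(bn, cn) <= quad + 1e-12 * abs(quad)) {
        return(list(beta = bn, icept = cn, L = L))
      }
      L <- L * 2
      if (L > 1e15) return(list(beta = b0, icept = c0v, L = L))
    }
  }

  for (iter in seq_len(opts$max_iter)) {
    st <- prox_step(yb, yc, L)
    L <- max(st$L / 2, 1e-8)      # allow the local curvature estimate to relax
    Fnew <- objective(st$beta, st$icept)
    if (Fnew > Fcur) {
      # accelerated step overshot: monotone fallback from the last accepted
      # iterate, with momentum restart
      st <- prox_step(beta, icept, max(L, 1))
      L <- max(st$L / 2, 1e-8)
      Fnew <- objective(st$beta, st$icept)
      tk <- 1
      yb <- st$beta; yc <- st$icept
      if (Fnew > Fcur) {
        # no further decrease representable at machine precision
        converged <- TRUE
        break
      }
    } else {
      tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
      mom <- (tk - 1) / tnew
      yb <- st$beta + mom * (st$beta - beta)
      yc <- st$icept + mom * (st$icept - icept)
      tk <- tnew
    }
    rel <- abs(Fcur - Fnew) / max(1, abs(Fnew))
    beta <- st$beta; icept <- st$icept
    Fcur <- Fnew
    trace <- c(trace, Fcur)
    if (rel < opts$tol) { converged <- TRUE; break }
  }

  structure(list(beta = beta, intercept = icept,
                 lambda1 = lambda1, lambda2 = lambda2,
                 lambda1_abs = l1, lambda2_abs = l2,
                 lambda_max = lmax,
                 groups = groups, feature_map = feature_map,
                 hypothesis_name = hypothesis_name,
                 objective = trace, iterations = iter,
                 converged = converged),
            class = "esl_model")
}

#' @export
print.esl_model <- function(x, ...) {
  nz <- sum(x$beta != 0)
  ng <- sum(.group_norms(x$beta, x$groups) > 0)
  cat("ESL model '", x$hypothesis_name, "': ", nz, "/", length(x$beta),
      " nonzero bit columns in ", ng, "/", nrow(x$groups),
      " group(s); lambda1 = ", x$lambda1, ", lambda2 = ", x$lambda2,
      "; objective = ", format(utils::tail(x$objective, 1)), "\n", sep = "")
  invisible(x)
}

#' Count groups with any nonzero coefficient
#'
#' @param model An `esl_model`.
#' @return Integer count.
#' @export
n_groups_selected <- function(model) {
  sum(.group_norms(model$beta, model$groups) > 0)
}
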