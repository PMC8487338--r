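#' Dichotomize graded items for 2PL calibration
#'
#' Graded items are converted to pass/fail at the item's 5th centile of
#' ranked raw scores: success is scoring strictly above the centile-rank
#' order statistic. Error-count items (where lower is better) are
#' direction-reversed before the rule is applied, so success still means
#' better performance. Already-binary items pass through unchanged.
#' Zero-variance binary items (all pass or all fail) cannot be calibrated
#' and are dropped with a listing.
#'
#' @param item_matrix Data frame/matrix of integer item scores, subjects in
#'   rows.
#' @param item_directions Named character vector per item: `"higher"`
#'   (higher score is better, default for unnamed items) or `"lower"`
#'   (error counts).
#' @param centile Dichotomization centile (percent, default 5).
#' @return List: `binary` (tibble of 0/1 responses), `dropped` (character),
#'   `thresholds` (tibble of item, direction, threshold used).
#' @export
dichotomize_items <- function(item_matrix, item_directions = NULL,
                              centile = 5) {
  m <- tibble::as_tibble(as.data.frame(item_matrix))
  n <- nrow(m)
  dirs <- setNames(rep("higher", ncol(m)), names(m))
  if (!is.null(item_directions)) {
    bad <- setdiff(names(item_directions), names(m))
    if (length(bad) > 0L) {
      abort(paste0("directions for unknown items: ",
                   paste(bad, collapse = ", ")))
    }
    dirs[names(item_directions)] <- item_directions
  }
  out <- list(); dropped <- character(); thr <- list()
  for (item in names(m)) {
    x <- m[[item]]
    is_binary <- all(x %in% c(0L, 1L))
    if (is_binary) {
      bin <- as.integer(x)
      threshold <- NA_real_
    } else {
      v <- if (dirs[[item]] == "lower") -x else x
      threshold <- sort(v)[ceiling(centile / 100 * n)]
      bin <- as.integer(v > threshold)
      if (dirs[[item]] == "lower") threshold <- -threshold
    }
    if (var(bin) == 0) {
      dropped <- c(dropped, item)
    } else {
      out[[item]] <- bin
    }
    thr[[item]] <- tibble::tibble(item = item, direction = dirs[[item]],
                                  already_binary = is_binary,
                                  threshold = threshold,
                                  dropped = var(bin) == 0)
  }
  if (length(out) == 0L) abort("all items dropped as zero-variance")
  list(binary = tibble::as_tibble(out), dropped = dropped,
       thresholds = dplyr::bind_rows(thr))
}

# fixed quadrature: equally spaced nodes on [-5, 5] with normalized
# standard-normal weights (the conventional fixed-grid MML approximation)
quadrature_grid <- function(n_nodes = 41, range = c(-5, 5)) {
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

# M-step inner solver: weighted logistic regression of expected correct
# counts r on nodes with totals nk; logit P = c0 + c1 * theta
mstep_item <- function(r, nk, nodes, c0, c1, max_iter = 50, tol = 1e-9) {
  for (it in seq_len(max_iter)) {
    p <- plogis(c0 + c1 * nodes)
    w <- nk * p * (1 - p)
    g <- c(sum(r - nk * p), sum((r - nk * p) * nodes))
    H <- matrix(c(sum(w), sum(w * nodes), sum(w * nodes),
                  sum(w * nodes^2)), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    c0 <- c0 + step[1]; c1 <- c1 + step[2]
    if (max(abs(step)) < tol) break
  }
  c(c0 = c0, c1 = c1)
}

#' Fit a two-parameter logistic IRT model
#'
#' Marginal maximum likelihood with a standard-normal latent trait,
#' estimated by EM over a fixed quadrature grid (41 equally spaced nodes on
#' \[-5, 5\] with normal weights). Item response probability is
#' `P = 1 / (1 + exp(-a (theta - b)))`. The E step computes each subject's
#' posterior over nodes; the M step maximizes each item's expected complete
#' log-likelihood by Newton-Raphson on the logit-linear parametrization
#' (`a = c1`, `b = -c0 / c1`). Convergence is declared when the largest
#' absolute parameter change drops below `tol`; the marginal log-likelihood
#' trace is retained and is non-decreasing across iterations.
#'
#' @param binary_matrix 0/1 matrix or data frame, subjects in rows, items in
#'   columns; no zero-variance items.
#' @param max_iter EM iteration cap (error with trace on non-convergence).
#' @param tol Parameter-change convergence threshold (default 1e-4).
#' @param n_nodes Number of quadrature nodes.
#' @return Object of class `irt_fit`: `items` tibble (`item`, `a`, `b`,
#'   `heywood` flag for |a| > 10), `loglik_trace`, `n_iter`, `converged`,
#'   `n_subjects`.
#' @export
fit_2pl <- function(binary_matrix, max_iter = 1000, tol = 1e-4,
                    n_nodes = 41) {
  X <- as.matrix(binary_matrix)
  if (!all(X %in% c(0, 1))) abort("binary_matrix must contain only 0/1")
  if (any(apply(X, 2, var) == 0)) {
    abort("zero-variance items present; dichotomize_items() drops them")
  }
  n <- nrow(X); J <- ncol(X)
  if (J < 2) abort("need at least 2 items")
  quad <- quadrature_grid(n_nodes)
  K <- n_nodes
  # init from classical difficulty
  pbar <- colMeans(X)
  c1 <- rep(1, J)
  c0 <- stats::qlogis(pmin(pmax(pbar, 0.01), 0.99))
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step: person x node log-likelihoods
    P <- plogis(outer(quad$nodes, c1) +
                  matrix(c0, K, J, byrow = TRUE))  # K x J
    logP <- log(P); log1P <- log1p(-P)
    ll_nk <- X %*% t(logP) + (1 - X) %*% t(log1P)  # n x K
    ll_nk <- sweep(ll_nk, 2, log(quad$weights), "+")
    mx <- apply(ll_nk, 1, max)
    lik <- exp(ll_nk - mx)
    marg <- rowSums(lik)
    loglik_trace <- c(loglik_trace, sum(log(marg) + mx))
    W <- lik / marg                                # posterior weights n x K
    nk <- colSums(W)                               # expected count per node
    R <- t(W) %*% X                                # K x J expected corrects
    # M step
    old <- c(c0, c1)
    for (j in seq_len(J)) {
      cc <- mstep_item(R[, j], nk, quad$nodes, c0[j], c1[j])
      c0[j] <- cc[1]; c1[j] <- cc[2]
    }
    if (max(abs(c(c0, c1) - old)) < tol) {
      converged <- TRUE
      break
    }
  }
  items <- tibble::tibble(
    item = colnames(X) %||% paste0("item", seq_len(J)),
    a = c1,
    b = ifelse(abs(c1) < 1e-6, NA_real_, -c0 / c1),
    heywood = abs(c1) > 10
  )
  fit <- structure(
    list(items = items, loglik_trace = loglik_trace,
         n_iter = length(loglik_trace), converged = converged,
         n_subjects = n, tol = tol, n_nodes = n_nodes),
    class = "irt_fit"
  )
  if (!converged) {
    cnd <- rlang::error_cnd(
      "phonenorms_irt_nonconvergence",
      message = paste0("EM did not converge within ", max_iter,
                       " iterations (max |change| still >= ", tol, ")"),
      fit = fit
    )
    rlang::cnd_signal(cnd)
  }
  fit
}

#' @export
print.irt_fit <- function(x, ...) {
  cat("<irt_fit> ", nrow(x$items), " items, ", x$n_subjects, " subjects; ",
      x$n_iter, " EM iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(x$items)
  invisible(x)
}

#' Classify calibrated items
#'
#' Adds the conventional flag columns: `discriminative` (a >= 1.5),
#' `highly_discriminative` (a >= 1.7; flags are cumulative, so a highly
#' discriminative item is also discriminative), and `difficult`
#' (b >= `difficulty_cut`, default 3 — the cut is a configurable convention,
#' not a universal standard).
#'
#' @param params An `irt_fit` or its `items` tibble.
#' @param discriminative_cut,highly_discriminative_cut,difficulty_cut
#'   Thresholds on `a`, `a`, and `b`.
#' @return Tibble of item parameters with logical flag columns.
#' @export
classify_items <- function(params, discriminative_cut = 1.5,
                           highly_discriminative_cut = 1.7,
                           difficulty_cut = 3) {
  items <- if (inherits(params, "irt_fit")) params$items else
    tibble::as_tibble(params)
  dplyr::mutate(
    items,
    discriminative = .data$a >= discriminative_cut,
    highly_discriminative = .data$a >= highly_discriminative_cut,
    difficult = !is.na(.data$b) & .data$b >= difficulty_cut
  )
}

#' @export
tidy.irt_fit <- function(x, ...) classify_items(x)

#' @export
glance.irt_fit <- function(x, ...) {
  tibble::tibble(
    n_items = nrow(x$items), n_subjects = x$n_subjects,
    loglik = tail(x$loglik_trace, 1), n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Plot item characteristic curves
#'
#' @param object An `irt_fit`.
#' @param theta_range Latent-trait range for the curves.
#' @param ... Unused.
#' @export
autoplot.irt_fit <- function(object, theta_range = c(-4, 4), ...) {
  theta <- seq(theta_range[1], theta_range[2], length.out = 201)
  df <- purrr::map_dfr(seq_len(nrow(object$items)), function(j) {
    tibble::tibble(
      item = object$items$item[j], theta = theta,
      p = plogis(object$items$a[j] * (theta - object$items$b[j]))
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$p,
                                   colour = .data$item)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta), y = "P(correct)",
                  title = "Item characteristic curves") +
    ggplot2::theme_minimal()
}
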