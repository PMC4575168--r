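#' Sitewise frequencies of natural homologs
#'
#' Computes a [frequency_matrix] from a multiple alignment of homologs.
#' Replicate (identical) aligned sequences are collapsed to a weight equal
#' to the square root of their number of occurrences, damping dominant
#' duplicates while retaining their repeated observation. Gap characters
#' (`-` or `.`) are excluded per site.
#'
#' @param alignment an `AAStringSet`, character vector of equal-length
#'   aligned sequences, or the path of an aligned FASTA file.
#' @param site_map named integer vector mapping reference site labels to
#'   alignment columns. Columns not mapped are ignored.
#' @return a [frequency_matrix] over `names(site_map)`.
#' @export
homolog_frequency_matrix <- function(alignment, site_map) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  if (methods::is(alignment, "AAStringSet"))
    alignment <- as.character(alignment)
  stopifnot(length(unique(nchar(alignment))) == 1)
  if (any(site_map < 1 | site_map > nchar(alignment[1])))
    stop("site_map columns outside the alignment", call. = FALSE)
  tab <- table(unname(alignment))
  seqs <- names(tab)
  wts <- sqrt(as.numeric(tab))
  mat <- .char_matrix(seqs)
  rows <- lapply(seq_along(site_map), function(i) {
    col <- mat[, site_map[i]]
    keep <- col %in% AA20
    if (!any(keep)) return(NULL)
    data.table(site = names(site_map)[i], aa = col[keep], w = wts[keep])
  })
  counts <- rbindlist(rows)[, .(w = sum(w)), by = .(site, aa)]
  frequency_matrix(counts, sites = names(site_map))
}

#' Read / write sites-by-amino-acid matrices as TSV
#'
#' The interchange format for frequency and stability matrices: one row per
#' site, 20 amino-acid columns, first column `site`.
#'
#' @param path file path.
#' @param m matrix with site rownames and [AA20] colnames.
#' @param frequency validate as a frequency matrix (rows sum to 1)?
#' @return `read_site_matrix` returns a matrix (a [frequency_matrix] when
#'   `frequency = TRUE`).
#' @export
read_site_matrix <- function(path, frequency = FALSE) {
  dt <- data.table::fread(path, sep = "\t")
  stopifnot(all(AA20 %in% names(dt)))
  m <- as.matrix(dt[, AA20, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  if (frequency) {
    stopifnot(all(abs(rowSums(m) - 1) < 1e-6))
    m <- structure(m, class = "frequency_matrix",
                   effective_weight = setNames(rep(1, nrow(m)),
                                               rownames(m)))
  }
  m
}

#' @rdname read_site_matrix
#' @export
write_site_matrix <- function(m, path) {
  dt <- data.table(site = rownames(m))
  for (a in AA20) dt[[a]] <- unclass(m)[, a]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Convert a stability matrix to a frequency input matrix
#'
#' Boltzmann weighting of per-site ddG(folding) values:
#' `f(site, aa) proportional to exp(-ddG / RT)`. The conversion the original
#' analysis used is unstated, so RT is exposed (default 0.59 kcal/mol,
#' ambient); any externally supplied stability-derived frequency matrix can
#' be used instead.
#'
#' @param sm sites x 20 matrix of ddG values (kcal/mol).
#' @param RT Boltzmann scale (> 0), kcal/mol.
#' @return a [frequency_matrix].
#' @export
stability_to_frequency <- function(sm, RT = 0.59) {
  stopifnot(RT > 0, all(is.finite(sm)))
  w <- exp(-sm / RT)
  m <- w / rowSums(w)
  structure(as.matrix(m), class = "frequency_matrix",
            effective_weight = setNames(rep(1, nrow(m)), rownames(m)))
}

#' Mutational tolerance per site
#'
#' The number of minimally destabilising substitutions per site: residues
#' with `ddG < threshold` (default 0.75 kcal/mol). The reference residue
#' has ddG 0 by definition and is always counted.
#'
#' @param sm sites x 20 ddG matrix.
#' @param threshold kcal/mol cutoff.
#' @return named integer vector of tolerated-residue counts.
#' @export
mutational_tolerance <- function(sm, threshold = 0.75) {
  stopifnot(is.finite(threshold))
  rowSums(sm < threshold)
}

#' Converged mean ddG from a pluggable stability oracle
#'
#' Repeatedly evaluates a stability oracle (e.g. a wrapped FoldX run) for
#' one (site, residue) on random library backgrounds until the running mean
#' has moved less than `tol` over the last `run` evaluations and more than
#' `min_n` evaluations have been made.
#'
#' @param oracle function `(site, residue)` returning one finite ddG value;
#'   any randomness over mutant backgrounds lives inside the oracle.
#' @param site,residue passed through to the oracle.
#' @param tol convergence tolerance in kcal/mol (default 0.2).
#' @param run number of consecutive evaluations that must stay within
#'   `tol` (default 5).
#' @param min_n minimum evaluations before convergence is declared
#'   (default 50, i.e. converges at n > 50).
#' @param max_n evaluation budget; exceeding it raises an error.
#' @return list with `mean`, `n` and the evaluation `values`.
#' @export
convergence_driver <- function(oracle, site, residue, tol = 0.2, run = 5,
                               min_n = 50, max_n = 5000) {
  vals <- numeric(0)
  means <- numeric(0)
  repeat {
    v <- oracle(site, residue)
    if (!is.finite(v)) stop("oracle returned a non-finite ddG",
                            call. = FALSE)
    vals <- c(vals, v)
    n <- length(vals)
    means <- c(means, mean(vals))
    if (n > min_n && n > run) {
      recent <- means[(n - run):n]
      if (max(recent) - min(recent) < tol)
        return(list(mean = means[n], n = n, values = vals))
    }
    if (n >= max_n)
      stop("ddG did not converge within ", max_n, " evaluations ",
           sprintf("(last running means: %s)",
                   paste(round(tail(means, run), 3), collapse = ", ")),
           call. = FALSE)
  }
}

#' Constrained linear fit of evolved sitewise distributions
#'
#' Fits the model `F(site, aa) = sum_k (alpha_k + beta_k * eps_site) *
#' f_k(site, aa)` to an objective frequency matrix by equality-constrained
#' linear least squares (closed-form KKT solution) with `sum(alpha) = 1`
#' and `sum(beta) = 0`, so effective weights sum to 1 at every exposure.
#' No sign constraints are imposed: boundary and negative weights are
#' reported, not forbidden.
#'
#' @param objective a [frequency_matrix]: the evolved sitewise amino-acid
#'   frequencies being explained.
#' @param inputs named list of >= 1 input frequency matrices `f_k` (e.g.
#'   complementarity, stability-derived, homolog) over the same sites.
#' @param eps named exposure vector (site -> value in `[0, 1]`) covering
#'   all fitted sites.
#' @return a `fit_result`: list with `alpha`, `beta` (named per input),
#'   `residual` (sum of squared errors), `fitted` matrix and `inputs_used`.
#' @export
fit_weights <- function(objective, inputs, eps) {
  k <- length(inputs)
  stopifnot(k >= 1)
  sites <- rownames(objective)
  for (f in inputs)
    if (!identical(rownames(f), sites))
      stop("input matrices must share the objective's site set",
           call. = FALSE)
  if (!all(sites %in% names(eps)))
    stop("exposure vector must cover every fitted site", call. = FALSE)
  eps <- eps[sites]
  stopifnot(all(eps >= 0 & eps <= 1))
  y <- as.vector(unclass(objective))
  e_long <- rep(eps, times = 20)
  X <- matrix(0, length(y), 2 * k)
  for (j in seq_len(k)) {
    fj <- as.vector(unclass(inputs[[j]]))
    X[, j] <- fj
    X[, k + j] <- fj * e_long
  }
  if (k == 1) {
    theta <- c(1, 0)  # forced by the constraints
  } else {
    A <- rbind(c(rep(1, k), rep(0, k)), c(rep(0, k), rep(1, k)))
    b <- c(1, 0)
    M <- rbind(cbind(2 * crossprod(X), t(A)),
               cbind(A, matrix(0, 2, 2)))
    rhs <- c(2 * crossprod(X, y), b)
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol) || rcond(M) < 1e-12)
      stop("non-identifiable weights: input matrices are rank deficient",
           call. = FALSE)
    theta <- sol[seq_len(2 * k)]
  }
  fitted <- X %*% theta
  nms <- if (!is.null(names(inputs))) names(inputs) else
    paste0("input", seq_len(k))
  structure(list(
    alpha = setNames(theta[seq_len(k)], nms),
    beta = setNames(theta[k + seq_len(k)], nms),
    residual = sum((fitted - y)^2),
    fitted = matrix(fitted, nrow(objective), 20,
                    dimnames = dimnames(objective)),
    sites = sites, eps = eps), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> residual =", format(x$residual, digits = 4), "\n")
  print(round(rbind(alpha = x$alpha, beta = x$beta), 4))
  invisible(x)
}

#' Effective weights at a given exposure
#'
#' `alpha_k + beta_k * eps`; by construction the effective weights sum to 1
#' at every exposure.
#'
#' @param fit a `fit_result`.
#' @param eps exposure value(s) in `[0, 1]`.
#' @return matrix (length(eps) x k) of effective weights.
#' @export
effective_weights <- function(fit, eps) {
  out <- outer(eps, fit$beta) + rep(1, length(eps)) %o% fit$alpha
  rownames(out) <- as.character(eps)
  out
}

#' z-score of a fit versus an unbiased control
#'
#' Quantifies how much better the informative inputs explain the objective
#' than uninformative ones: the control refits the same model with every
#' input replaced by the uniform 5\%-each matrix, and the difference of
#' residuals is scaled by its bootstrap standard deviation over sites
#' (both fits recomputed per site-resample).
#'
#' @param fit a `fit_result` from [fit_weights()].
#' @param objective,inputs,eps as passed to [fit_weights()].
#' @param n_boot bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @return list with `z`, `residual_model`, `residual_control`, `sd`.
#' @export
zscore_vs_unbiased <- function(fit, objective, inputs, eps, n_boot = 200,
                               seed = 1) {
  sites <- rownames(objective)
  if (length(sites) < 5)
    stop("need at least 5 sites for the bootstrap", call. = FALSE)
  # with every input uniform, any constrained weights give F = uniform, so
  # the control residual needs no fitting
  obj_m <- unclass(objective)
  control_res <- function(idx) sum((obj_m[idx, , drop = FALSE] - 0.05)^2)
  sub_fm <- function(fm, idx) {
    m <- unclass(fm)[idx, , drop = FALSE]
    rownames(m) <- paste0("s", seq_along(idx))
    structure(m, class = "frequency_matrix")
  }
  refit <- function(idx) {
    obj <- sub_fm(objective, idx)
    inps <- lapply(inputs, sub_fm, idx = idx)
    ep <- setNames(fit$eps[idx], rownames(obj))
    fit_weights(obj, inps, ep)$residual
  }
  all_idx <- seq_along(sites)
  res_model <- fit$residual
  res_control <- control_res(all_idx)
  diffs <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample(all_idx, replace = TRUE)
    rm_ <- tryCatch(refit(idx), error = function(e) NA_real_)
    control_res(idx) - rm_
  }, numeric(1)))
  s <- sd(diffs, na.rm = TRUE)
  list(z = (res_control - res_model) / s,
       residual_model = res_model, residual_control = res_control, sd = s)
}
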