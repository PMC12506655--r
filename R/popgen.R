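# HWE genotype priors for ref-allele frequency f, genotypes (RR, RA, AA).
hwe_prior <- function(f) {
  cbind(f^2, 2 * f * (1 - f), (1 - f)^2)
}

#' Maximum-likelihood allele frequencies from genotype likelihoods
#'
#' Per-site EM under Hardy-Weinberg equilibrium, treating each diploid
#' individual's normalized GL triplet as the unit of evidence (the
#' Beagle-input estimation path). E-step: posterior genotype weights
#' proportional to GL x HWE prior; M-step: f becomes the mean expected
#' ref-allele dosage divided by 2. All sites are iterated jointly
#' (vectorised); each site stops when its frequency moves less than
#' \code{tol}.
#'
#' @param gl a \code{gl_set} covering one or more individuals over a common
#'   site set.
#' @param tol convergence threshold on |change in f| (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @param f_init frequency reported, with \code{flat_flag}, at sites where
#'   every individual's GL is uninformative (default 0.5). Informative sites
#'   are initialized from the best point of a coarse likelihood grid: the
#'   per-site likelihood is a polynomial in f that can be multimodal for
#'   small samples, and EM only climbs to the local optimum of its starting
#'   basin.
#' @return data.frame per site: \code{chrom}, \code{pos}, \code{f_ref},
#'   \code{n_eff} (individuals with informative GLs), \code{iterations},
#'   \code{loglik}, \code{flat_flag}, \code{converged}.
#' @export
estimate_af_ml <- function(gl, tol = 1e-6, max_iter = 200, f_init = 0.5) {
  m <- gl_matrices(gl)
  L <- m$L  # list of three sites x individuals matrices
  n_sites <- nrow(L$rr)
  n_ind <- ncol(L$rr)
  if (n_ind < 1) stop("at least one individual required")
  # informative = triplet not equal within numerical tolerance
  flat_ind <- abs(L$rr - L$ra) < 1e-12 & abs(L$ra - L$aa) < 1e-12
  n_eff <- as.integer(rowSums(!flat_ind))
  flat_flag <- n_eff == 0L
  f <- rep(f_init, n_sites)
  if (any(!flat_flag)) {
    coarse <- seq(0.005, 0.995, length.out = 34)
    ll_grid <- vapply(coarse, function(fc) af_loglik(L, fc), numeric(n_sites))
    if (n_sites == 1) ll_grid <- matrix(ll_grid, nrow = 1)
    f[!flat_flag] <- coarse[max.col(ll_grid[!flat_flag, , drop = FALSE],
                                    ties.method = "first")]
  }
  iters <- integer(n_sites)
  active <- !flat_flag
  it <- 0
  while (any(active) && it < max_iter) {
    it <- it + 1
    fa <- f[active]
    w_rr <- L$rr[active, , drop = FALSE] * fa^2
    w_ra <- L$ra[active, , drop = FALSE] * (2 * fa * (1 - fa))
    w_aa <- L$aa[active, , drop = FALSE] * (1 - fa)^2
    tot <- w_rr + w_ra + w_aa
    dose <- (2 * w_rr + w_ra) / tot
    f_new <- rowMeans(dose) / 2
    moved <- abs(f_new - fa) >= tol
    iters[active] <- it
    f[active] <- f_new
    active[active] <- moved
  }
  loglik <- af_loglik(L, f)
  data.frame(chrom = m$chrom, pos = m$pos, f_ref = f, n_eff = n_eff,
             iterations = iters, loglik = loglik, flat_flag = flat_flag,
             converged = !active, row.names = NULL)
}

af_loglik <- function(L, f) {
  rowSums(log(L$rr * f^2 + L$ra * 2 * f * (1 - f) + L$aa * (1 - f)^2))
}

# Reshape a gl_set into sites x individuals matrices, checking alignment.
gl_matrices <- function(gl) {
  individuals <- unique(gl$individual)
  key <- paste(gl$chrom, gl$pos)
  sites <- unique(key[gl$individual == individuals[1]])
  if (nrow(gl) != length(sites) * length(individuals))
    stop("gl_set is ragged across individuals")
  si <- match(key, sites)
  ii <- match(gl$individual, individuals)
  shape <- function(v) {
    mm <- matrix(NA_real_, length(sites), length(individuals))
    mm[cbind(si, ii)] <- v
    if (anyNA(mm)) stop("gl_set does not cover all individual x site pairs")
    mm
  }
  first <- gl[gl$individual == individuals[1], , drop = FALSE]
  list(L = list(rr = shape(gl$l_rr), ra = shape(gl$l_ra),
                aa = shape(gl$l_aa)),
       chrom = first$chrom, pos = first$pos, individuals = individuals)
}

#' Per-site f2 population differentiation
#'
#' Squared allele-frequency difference between two populations. The plain
#' mode is \code{(f1 - f2)^2}; the corrected mode additionally subtracts a
#' finite-sample heterozygosity term \code{h/(n - 1)} per population, with
#' \code{h = f(1-f) n/(n-1)}, when sample sizes are supplied. Comparisons
#' should use the same mode on both sides; plain is the default.
#'
#' @param f1,f2_ reference-allele frequencies in [0, 1] (vectorised).
#' @param n1,n2 sample sizes (same units for both populations), or NULL for
#'   the plain statistic.
#' @return Numeric vector of per-site f2 values.
#' @export
f2_per_site <- function(f1, f2_, n1 = NULL, n2 = NULL) {
  if (any(f1 < 0 | f1 > 1 | f2_ < 0 | f2_ > 1, na.rm = TRUE))
    stop("frequencies must be in [0, 1]")
  plain <- (f1 - f2_)^2
  if (is.null(n1) || is.null(n2)) return(plain)
  if (any(n1 <= 1) || any(n2 <= 1))
    stop("corrected f2 requires sample sizes > 1")
  h1 <- f1 * (1 - f1) * n1 / (n1 - 1)
  h2 <- f2_ * (1 - f2_) * n2 / (n2 - 1)
  plain - h1 / (n1 - 1) - h2 / (n2 - 1)
}

#' Supervised admixture-proportion EM for one individual
#'
#' Fits the supervised PSD model from genotype likelihoods: the individual's
#' two allele copies at each site are drawn from K source clusters with
#' proportions q, the per-site ref-allele probability is
#' \code{p = sum_k q_k f_k}, and genotypes follow HWE at p. Source
#' frequencies are fixed (known or pre-estimated); only q is estimated, by
#' EM on the expected per-allele-copy ancestry assignments, from the uniform
#' initialization q = (1/K, ..., 1/K).
#'
#' @param gl a \code{gl_set} for a single individual.
#' @param sources sites x K matrix of source ref-allele frequencies, rows
#'   aligned with the (sorted) sites of \code{gl}.
#' @param tol convergence threshold on max |change in q| (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @param eps frequency clamp keeping source frequencies inside (0, 1) so
#'   fixed sites cannot zero the likelihood (default 1e-6).
#' @return list of class \code{admixture_result}: \code{individual},
#'   \code{q} (named K-vector on the simplex), \code{loglik},
#'   \code{iterations}, \code{flat_flag} (identical sources at every site:
#'   the likelihood is flat in q and the initialization is returned),
#'   \code{converged}.
#' @export
estimate_admixture_em <- function(gl, sources, tol = 1e-6, max_iter = 200,
                                  eps = 1e-6) {
  if (length(unique(gl$individual)) != 1)
    stop("estimate_admixture_em takes a single individual's gl_set")
  sources <- as.matrix(sources)
  K <- ncol(sources)
  if (K < 2) stop("at least two source populations required")
  if (nrow(sources) != nrow(gl))
    stop("sources and gl_set must cover the same sites in the same order")
  Fk <- pmin(pmax(sources, eps), 1 - eps)
  q <- rep(1 / K, K)
  names(q) <- colnames(sources) %||% paste0("q", seq_len(K))
  flat <- all(apply(Fk, 1, function(row) max(row) - min(row)) < 1e-12)
  if (flat) {
    ll <- admix_loglik(gl, Fk, q)
    return(structure(list(individual = gl$individual[1], q = q,
                          loglik = ll, iterations = 0L, flat_flag = TRUE,
                          converged = TRUE),
                     class = "admixture_result"))
  }
  if (K == 2) {
    # coarse 1-D likelihood scan picks the global basin before EM
    coarse <- seq(0.005, 0.995, length.out = 34)
    llg <- vapply(coarse, function(q1) admix_loglik(gl, Fk, c(q1, 1 - q1)),
                  numeric(1))
    q <- c(coarse[which.max(llg)], 1 - coarse[which.max(llg)])
    names(q) <- colnames(Fk) %||% paste0("q", seq_len(K))
  }
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    p <- as.numeric(Fk %*% q)
    w <- cbind(gl$l_rr * p^2, gl$l_ra * 2 * p * (1 - p),
               gl$l_aa * (1 - p)^2)
    w <- w / rowSums(w)
    e_ref <- 2 * w[, 1] + w[, 2]   # expected ref-allele copies
    e_alt <- 2 * w[, 3] + w[, 2]
    # split each expected copy across sources
    a_ref <- (Fk * rep(q, each = nrow(Fk))) / p
    a_alt <- ((1 - Fk) * rep(q, each = nrow(Fk))) / (1 - p)
    counts <- colSums(a_ref * e_ref + a_alt * e_alt)
    q_new <- counts / sum(counts)
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  names(q) <- colnames(Fk) %||% paste0("q", seq_len(K))
  structure(list(individual = gl$individual[1], q = q,
                 loglik = admix_loglik(gl, Fk, q), iterations = it,
                 flat_flag = FALSE, converged = converged),
            class = "admixture_result")
}

admix_loglik <- function(gl, Fk, q) {
  p <- as.numeric(Fk %*% q)
  sum(log(gl$l_rr * p^2 + gl$l_ra * 2 * p * (1 - p) +
            gl$l_aa * (1 - p)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean admixture proportions across target individuals
#'
#' @param results list of \code{admixture_result} objects (one per
#'   individual).
#' @return Named numeric K-vector: the arithmetic mean of the per-individual
#'   proportions (sums to 1).
#' @export
mean_population_admixture <- function(results) {
  if (length(results) == 0) stop("at least one individual required")
  qm <- do.call(rbind, lapply(results, function(r) r$q))
  colMeans(qm)
}

#' Read / write a source-frequency TSV
#'
#' Columns: CHROM POS REF ALT then one frequency column per source.
#'
#' @param path file path.
#' @param panel optional \code{\link{snp_panel}} to align rows against.
#' @return list with \code{panel} columns and \code{freqs} matrix.
#' @export
read_source_freqs <- function(path, panel = NULL) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  freqs <- as.matrix(x[, -(1:4), drop = FALSE])
  if (!is.null(panel)) {
    idx <- match(paste(panel$chrom, panel$pos), paste(x[[1]], x[[2]]))
    if (anyNA(idx)) stop("source frequencies missing for some panel sites")
    x <- x[idx, , drop = FALSE]
    freqs <- freqs[idx, , drop = FALSE]
  }
  list(chrom = as.character(x[[1]]), pos = as.integer(x[[2]]),
       ref = x[[3]], alt = x[[4]], freqs = freqs)
}
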