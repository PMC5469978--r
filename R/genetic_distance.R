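#' Construct a labelled distance matrix
#'
#' The exchange format between pipeline stages: a symmetric population x
#' population matrix with zero diagonal and a metric tag (`dps`, `fst`,
#' `geographic`, or `cgd`). `Inf` entries are allowed for `cgd`
#' (disconnected pairs); small negative `fst` entries from the
#' variance-component estimator are reported as-is.
#'
#' @param values symmetric numeric matrix, zero diagonal
#' @param labels population labels (defaults to rownames)
#' @param metric one of `"dps"`, `"fst"`, `"geographic"`, `"cgd"`
#' @return a `dist_matrix`
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        metric = c("dps", "fst", "geographic", "cgd")) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(values)))
  stopifnot(nrow(values) == ncol(values), length(labels) == nrow(values))
  finite <- values[is.finite(values)]
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12, na.rm = TRUE))
    stop("distance matrix must have zero diagonal")
  if (metric == "dps" && (min(finite) < -1e-9 || max(finite) > 1 + 1e-9))
    stop("dps values must lie in [0, 1]")
  if (metric == "geographic" && min(finite) < 0)
    stop("geographic distances must be non-negative")
  dimnames(values) <- list(labels, labels)
  structure(values, metric = metric, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d populations\n", attr(x, "metric"), nrow(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

lower_tri <- function(m) m[lower.tri(m)]

#' Per-population, per-locus allele frequencies
#'
#' Counts alleles over non-missing diploid calls: a population with `n`
#' scored individuals at a locus contributes `2n` allele observations.
#' Each frequency vector spans the full allele namespace observed at that
#' locus across all populations and sums to 1; a population with no
#' scored individuals at a locus gets an all-`NA` vector (flagged absent).
#'
#' @param table a `genotype_table`
#' @return list with elements `freq` (list: locus -> population x allele
#'   frequency matrix), `counts` (same shape, allele counts), and `n_typed`
#'   (locus -> named vector of scored individuals per population)
#' @export
allele_frequencies <- function(table) {
  loci <- loci_names(table)
  pops <- unique(table$population)
  freq <- counts <- vector("list", length(loci))
  names(freq) <- names(counts) <- loci
  n_typed <- vector("list", length(loci))
  names(n_typed) <- loci
  for (lc in loci) {
    a1 <- table[[paste0(lc, ".1")]]
    a2 <- table[[paste0(lc, ".2")]]
    alleles <- sort(unique(stats::na.omit(c(a1, a2))))
    cnt <- matrix(0, nrow = length(pops), ncol = length(alleles),
                  dimnames = list(pops, alleles))
    nt <- stats::setNames(integer(length(pops)), pops)
    for (pop in pops) {
      sel <- table$population == pop & !is.na(a1)
      nt[pop] <- sum(sel)
      if (any(sel)) {
        tab <- table(factor(c(a1[sel], a2[sel]), levels = alleles))
        cnt[pop, ] <- as.numeric(tab)
      }
    }
    f <- cnt / rowSums(cnt)
    f[rowSums(cnt) == 0, ] <- NA_real_
    freq[[lc]] <- f
    counts[[lc]] <- cnt
    n_typed[[lc]] <- nt
  }
  all_missing <- vapply(pops, function(pop)
    all(vapply(loci, function(lc) all(is.na(freq[[lc]][pop, ])), logical(1))),
    logical(1))
  if (any(all_missing))
    stop("population(s) with no scored calls at any locus: ",
         paste(pops[all_missing], collapse = ", "))
  list(freq = freq, counts = counts, n_typed = n_typed, populations = pops)
}

#' Proportion-of-shared-alleles distance (population level)
#'
#' `D_PS(i,j) = 1 - (1/L') sum_loci sum_alleles min(f_i, f_j)` where `L'`
#' counts loci scored in both populations. This is the population-frequency
#' form of the shared-allele distance (the population-level statistic of
#' Microsatellite Analyzer), not a mean over individual pairs.
#'
#' @param table a `genotype_table`
#' @return a `dist_matrix` with metric `"dps"`
#' @export
dps_matrix <- function(table) {
  af <- allele_frequencies(table)
  pops <- af$populations
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    shared <- 0
    lp <- 0L
    for (lc in names(af$freq)) {
      fi <- af$freq[[lc]][i, ]
      fj <- af$freq[[lc]][j, ]
      if (anyNA(fi) || anyNA(fj)) next
      shared <- shared + sum(pmin(fi, fj))
      lp <- lp + 1L
    }
    if (lp == 0L)
      stop(sprintf("no locus scored in both '%s' and '%s'", pops[i], pops[j]))
    d[i, j] <- d[j, i] <- 1 - shared / lp
  }
  d[abs(d) < 1e-12] <- 0
  dist_matrix(pmin(pmax(d, 0), 1), pops, "dps")
}

# Weir-Cockerham variance components for one allele at one locus,
# two populations. Returns c(a, b, c).
wc_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise multilocus Weir-Cockerham theta (F_ST)
#'
#' For each population pair, per-allele variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) are summed over alleles and loci; theta = sum(a) /
#' sum(a + b + c). Negative estimates are reported as-is (not truncated).
#' A pair monomorphic across all loci yields `NA` with a warning.
#'
#' @param table a `genotype_table`
#' @return a `dist_matrix` with metric `"fst"`
#' @export
fst_matrix <- function(table) {
  pops <- unique(table$population)
  if (length(pops) < 2L) stop("need at least two populations")
  loci <- loci_names(table)
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    num <- den <- 0
    for (lc in loci) {
      a1 <- table[[paste0(lc, ".1")]]
      a2 <- table[[paste0(lc, ".2")]]
      sel1 <- table$population == pops[i] & !is.na(a1)
      sel2 <- table$population == pops[j] & !is.na(a1)
      n1 <- sum(sel1); n2 <- sum(sel2)
      if (n1 < 1L || n2 < 1L) next
      alleles <- unique(c(a1[sel1], a2[sel1], a1[sel2], a2[sel2]))
      if (length(alleles) < 2L) next
      for (al in alleles) {
        p1 <- (sum(a1[sel1] == al) + sum(a2[sel1] == al)) / (2 * n1)
        p2 <- (sum(a1[sel2] == al) + sum(a2[sel2] == al)) / (2 * n2)
        h1 <- sum(xor(a1[sel1] == al, a2[sel1] == al)) / n1
        h2 <- sum(xor(a1[sel2] == al, a2[sel2] == al)) / n2
        comp <- wc_components(p1, p2, h1, h2, n1, n2)
        num <- num + comp["a"]
        den <- den + sum(comp)
      }
    }
    if (den == 0) {
      warning(sprintf("pair (%s, %s) monomorphic at all loci: theta undefined",
                      pops[i], pops[j]))
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- num / den
    }
  }
  dist_matrix(d, pops, "fst")
}

#' Pairwise Euclidean geographic distances
#'
#' Expects projected planar coordinates in metres. Raw lon/lat degrees are
#' rejected; project first (see [equirectangular()]).
#'
#' @param sites a `site_table` (only `included` rows are used)
#' @param include_all use excluded sites too
#' @return a `dist_matrix` with metric `"geographic"` (metres)
#' @export
geographic_matrix <- function(sites, include_all = FALSE) {
  s <- if (include_all) sites else sites[sites$included, , drop = FALSE]
  if (all(abs(s$x) <= 180) && all(abs(s$y) <= 90))
    stop("coordinates look like lon/lat degrees; project to planar metres ",
         "first (e.g. equirectangular())")
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  dist_matrix(d, s$population, "geographic")
}

#' Equirectangular projection of lon/lat to planar metres
#' @param lon,lat coordinates in degrees
#' @param lat0 reference latitude (degrees) for the cos scaling
#' @return data.frame with x, y in metres
#' @export
equirectangular <- function(lon, lat, lat0 = mean(lat)) {
  R <- 6371008.8
  data.frame(x = R * (lon * pi / 180) * cos(lat0 * pi / 180),
             y = R * (lat * pi / 180))
}

#' Pearson correlation of two distance matrices
#'
#' Computed over the lower-triangle entries. Matrices must share labels in
#' the same order; a constant matrix is an error.
#'
#' @param a,b `dist_matrix` objects
#' @return Pearson r
#' @export
matrix_correlation <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("distance matrices must share labels in the same order")
  va <- lower_tri(a); vb <- lower_tri(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("matrix correlation undefined for a constant matrix")
  stats::cor(va, vb)
}

#' Mantel test between two distance matrices
#'
#' Permutes rows and columns of `b` jointly. One-tailed by default
#' (positive association, the isolation-by-distance convention);
#' p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1).
#'
#' @param a,b `dist_matrix` objects with matching labels
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return list with `r`, `p`, `n_perm`, `alternative`
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 99)
  r_obs <- matrix_correlation(a, b)
  n <- nrow(b)
  va <- lower_tri(a)
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(va, lower_tri(unclass(b)[idx, idx]))
  }, numeric(1))
  exceed <- if (alternative == "greater") sum(r_perm >= r_obs)
            else sum(abs(r_perm) >= abs(r_obs))
  list(r = r_obs, p = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm, alternative = alternative)
}

#' Write a distance matrix as labelled CSV plus long-format pair table
#' @param d a `dist_matrix`
#' @param path CSV path for the square matrix; the pair table goes to
#'   `<path-sans-ext>_pairs.csv`
#' @export
write_dist_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path, row.names = TRUE)
  idx <- which(lower.tri(d), arr.ind = TRUE)
  pairs <- data.frame(pop_i = rownames(d)[idx[, "row"]],
                      pop_j = colnames(d)[idx[, "col"]],
                      value = d[idx])
  utils::write.csv(pairs, sub("\\.csv$", "_pairs.csv", path), row.names = FALSE)
  invisible(path)
}
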