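## Low-input proteomics statistics: valid-value filtering, downshifted-
## normal imputation, s0-moderated two-group tests and one-way ANOVA with
## permutation-based FDR, Fisher-exact term enrichment with BH correction,
## and row standardization for heat maps.

#' Filter a protein matrix for decoys, contaminants and missingness
#'
#' Removes proteins flagged reverse/contaminant/site-only, converts zeros to
#' missing (quantification software reports non-detections as 0), and keeps
#' proteins whose missing-value fraction is at most `max_missing_frac`
#' (default 0.30, i.e. "30% or less missing values").
#'
#' @param m a [ProteinMatrix-class].
#' @param max_missing_frac maximum tolerated missing fraction in `[0, 1]`.
#' @param zeros_as_missing treat exact zeros as missing before filtering.
#' @return the filtered [ProteinMatrix-class].
#' @export
filterMatrix <- function(m, max_missing_frac = 0.30,
                         zeros_as_missing = TRUE) {
  stopifnot(is(m, "ProteinMatrix"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  rd <- SummarizedExperiment::rowData(m)
  keep <- !(rd$reverse | rd$contaminant | rd$siteOnly)
  m <- m[keep, ]
  v <- intensities(m)
  if (zeros_as_missing) v[v == 0] <- NA_real_
  frac <- rowMeans(is.na(v))
  m <- m[frac <= max_missing_frac, ]
  v <- v[frac <= max_missing_frac, , drop = FALSE]
  SummarizedExperiment::assay(m, "log2intensity") <- v
  m
}

#' Downshifted-normal imputation of missing values
#'
#' Each missing cell is drawn from a normal distribution derived from its
#' sample column's observed values: mean `mu - downshift * sigma` and s.d.
#' `width * sigma` (defaults width 0.3, downshift 1.8) — narrowed and
#' left-shifted to mimic below-detection-limit intensities. Per-column
#' imputation is the default; `scope = "global"` uses the whole-matrix
#' moments instead. Seeded and reproducible.
#'
#' @param m a [ProteinMatrix-class].
#' @param width s.d. shrink factor.
#' @param downshift shift in column-s.d. units.
#' @param seed RNG seed.
#' @param scope `"column"` (default) or `"global"`.
#' @return a complete [ProteinMatrix-class] (no missing values).
#' @export
imputeDownshift <- function(m, width = 0.3, downshift = 1.8, seed = 1L,
                            scope = c("column", "global")) {
  stopifnot(is(m, "ProteinMatrix"))
  scope <- match.arg(scope)
  v <- intensities(m)
  withSeed(seed, {
    if (scope == "global") {
      obs <- v[!is.na(v)]
      if (length(obs) < 2L) stop("not enough observed values to impute")
      mu <- mean(obs); sg <- stats::sd(obs)
      miss <- which(is.na(v))
      v[miss] <- stats::rnorm(length(miss), mu - downshift * sg, width * sg)
    } else {
      for (j in seq_len(ncol(v))) {
        obs <- v[!is.na(v[, j]), j]
        if (length(obs) < 2L)
          stop("column ", colnames(v)[j],
               " has fewer than 2 observed values")
        mu <- mean(obs); sg <- stats::sd(obs)
        miss <- which(is.na(v[, j]))
        if (length(miss))
          v[miss, j] <- stats::rnorm(length(miss), mu - downshift * sg,
                                     width * sg)
      }
    }
  })
  SummarizedExperiment::assay(m, "log2intensity") <- v
  m
}

## Internal: pick out a complete matrix + group vector
.statInput <- function(m) {
  v <- intensities(m)
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  list(v = v, groups = sampleGroups(m))
}

#' s0-moderated two-sample t statistic per protein
#'
#' `d = (mean_a - mean_b) / (s0 + se)` where `se` is the pooled-variance
#' two-sample standard error (n-1 denominator). The constant `s0` (default
#' 0.1) damps the statistic of low-variance proteins; `s0 = 0` recovers the
#' classical Student t exactly. Proteins with zero variance in both groups
#' and identical means score 0.
#'
#' @param m a complete [ProteinMatrix-class].
#' @param groups length-2 character: the two group labels (a, b), compared
#'   as a minus b.
#' @param s0 moderation constant.
#' @return data.frame: `protein`, `mean_a`, `mean_b`, `diff` (log2 FC),
#'   `se`, `statistic`.
#' @export
s0Ttest <- function(m, groups = NULL, s0 = 0.1) {
  inp <- .statInput(m)
  if (is.null(groups)) groups <- unique(inp$groups)[1:2]
  stopifnot(length(groups) == 2L)
  sel_a <- inp$groups == groups[1L]; sel_b <- inp$groups == groups[2L]
  if (sum(sel_a) < 2L || sum(sel_b) < 2L)
    stop("each group needs >= 2 samples")
  d <- s0TStat(inp$v[, sel_a, drop = FALSE], inp$v[, sel_b, drop = FALSE], s0)
  data.frame(protein = rownames(inp$v), d, row.names = NULL)
}

## Vectorized core; returns data.frame columns mean_a, mean_b, diff, se,
## statistic.  Used directly by the permutation loop.
s0TStat <- function(a, b, s0) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- ma - mb
  denom <- s0 + se
  stat <- ifelse(denom == 0, 0, diff / ifelse(denom == 0, 1, denom))
  data.frame(mean_a = ma, mean_b = mb, diff = diff, se = se,
             statistic = stat)
}

#' One-way ANOVA F statistic per protein
#'
#' Classical one-way F across all groups, vectorized over proteins. A
#' variance floor of 1e-12 guards the degenerate all-identical case. Feeds
#' [permutationFDR()]; for exactly two groups, `F = t^2`.
#'
#' @param m a complete [ProteinMatrix-class].
#' @param groups optional subset of group labels to include.
#' @return data.frame: `protein`, per-group means, `F`.
#' @export
anovaF <- function(m, groups = NULL) {
  inp <- .statInput(m)
  if (is.null(groups)) groups <- unique(inp$groups)
  sel <- inp$groups %in% groups
  v <- inp$v[, sel, drop = FALSE]
  f <- anovaFStat(v, inp$groups[sel])
  gm <- vapply(groups, function(g)
    rowMeans(v[, inp$groups[sel] == g, drop = FALSE]),
    numeric(nrow(v)))
  colnames(gm) <- paste0("mean_", groups)
  data.frame(protein = rownames(v), gm, F = f, row.names = NULL)
}

anovaFStat <- function(v, groups, floor = 1e-12) {
  g <- unique(groups)
  k <- length(g)
  n <- ncol(v)
  stopifnot(k >= 2L)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  grand <- rowMeans(v)
  ssb <- 0; ssw <- 0
  for (gi in g) {
    sel <- groups == gi
    mg <- rowMeans(v[, sel, drop = FALSE])
    ssb <- ssb + sum(sel) * (mg - grand)^2
    ssw <- ssw + rowSums((v[, sel, drop = FALSE] - mg)^2)
  }
  (ssb / (k - 1L)) / (ssw / (n - k) + floor)
}

#' Permutation-based FDR for the s0 t-test or ANOVA
#'
#' Recomputes the chosen statistic under random group-label permutations and
#' estimates, for each symmetric cutoff `c` on the absolute statistic,
#' `FDR(c) = (average over permutations of #{|stat_perm| > c}) /
#' max(1, #{|stat_obs| > c})`. Cutoffs are the observed absolute
#' statistics; a protein is called at cutoff `c` iff its statistic strictly
#' exceeds `c`, its q-value is the smallest estimated FDR over the cutoffs
#' that call it (monotone non-increasing in the statistic), and proteins
#' with `q <= target_fdr` are flagged.
#'
#' The permutation counts can be aggregated by their mean (default) or
#' median. The median looks robust but is unstable exactly where it
#' matters: at extreme cutoffs the per-permutation count is a small
#' integer, and a median of 0 declares an estimated FDR of 0 for the top
#' protein whenever half the permutations produce no exceedance — which
#' happens often enough under a complete null to break error control. The
#' mean keeps the contribution of every permutation (including the identity
#' relabelling, which is always part of the enumerated set) and retains
#' calibration; see the methods vignette. All distinct two-group
#' assignments are enumerated when there are at most `n_perm` of them;
#' otherwise `n_perm` random permutations are drawn under `seed`.
#'
#' @param m a complete [ProteinMatrix-class].
#' @param statistic `"s0_ttest"` (two groups) or `"anova_F"`.
#' @param groups group labels to use (two for the t-test; defaults to all).
#' @param target_fdr nominal FDR (default 0.05).
#' @param n_perm permutation budget (default 250).
#' @param s0 moderation constant for the t statistic.
#' @param estimator aggregation of the per-permutation exceedance counts:
#'   `"mean"` (default) or `"median"`.
#' @param seed RNG seed.
#' @return data.frame: per protein the statistic columns of the underlying
#'   test plus `q` and `significant`.
#' @export
permutationFDR <- function(m, statistic = c("s0_ttest", "anova_F"),
                           groups = NULL, target_fdr = 0.05,
                           n_perm = 250L, s0 = 0.1,
                           estimator = c("mean", "median"), seed = 1L) {
  statistic <- match.arg(statistic)
  estimator <- match.arg(estimator)
  inp <- .statInput(m)
  if (is.null(groups))
    groups <- if (statistic == "s0_ttest") unique(inp$groups)[1:2]
      else unique(inp$groups)
  sel <- inp$groups %in% groups
  v <- inp$v[, sel, drop = FALSE]
  glab <- inp$groups[sel]
  if (statistic == "s0_ttest") {
    stopifnot(length(groups) == 2L)
    base <- data.frame(protein = rownames(v),
                       s0TStat(v[, glab == groups[1L], drop = FALSE],
                               v[, glab == groups[2L], drop = FALSE], s0),
                       row.names = NULL)
    obs <- abs(base$statistic)
    statFun <- function(lab)
      abs(s0TStat(v[, lab == groups[1L], drop = FALSE],
                  v[, lab == groups[2L], drop = FALSE], s0)$statistic)
  } else {
    base <- anovaF(m, groups)
    obs <- abs(base$F)
    statFun <- function(lab) abs(anovaFStat(v, lab))
  }
  perms <- permuteLabels(glab, n_perm, seed)
  if (length(perms) < 2L)
    stop("too few samples: fewer than 2 distinct label permutations")
  permMat <- vapply(perms, statFun, numeric(nrow(v)))
  ## candidate cutoffs are the observed |stat| values; a protein is called
  ## at cutoff c iff its |stat| is strictly greater than c
  cuts <- sort(unique(obs))
  obs_sorted <- sort(obs)
  n_above <- length(obs) - findInterval(cuts, obs_sorted)
  counts <- matrix(apply(permMat, 2L, function(pv) {
    pv <- sort(pv)
    length(pv) - findInterval(cuts, pv)
  }), nrow = length(cuts))
  agg_counts <- if (estimator == "median") apply(counts, 1L, stats::median)
    else rowMeans(counts)
  fdr_hat <- agg_counts / pmax(1L, n_above)
  ## q for a protein = min estimated FDR over the cutoffs that call it,
  ## i.e. cutoffs strictly below its statistic; the prefix-min over
  ## ascending cutoffs makes q monotone non-increasing in |stat|
  prefmin <- cummin(fdr_hat)
  ## index of the largest cutoff strictly below each observed value
  j <- vapply(obs, function(u) {
    k <- findInterval(u, cuts)
    if (k >= 1L && cuts[k] == u) k - 1L else k
  }, integer(1))
  q <- ifelse(j >= 1L, pmin(prefmin[pmax(j, 1L)], 1), 1)
  out <- base
  out$q <- q
  out$significant <- q <= target_fdr
  out
}

## Distinct group-label permutations (list of label vectors). For two
## balanced/unbalanced groups all distinct assignments are enumerated when
## feasible; otherwise random draws.
permuteLabels <- function(glab, n_perm, seed) {
  n <- length(glab)
  tab <- table(glab)
  if (length(tab) == 2L) {
    na <- tab[[1L]]
    total <- choose(n, na)
    if (total <= n_perm) {
      idx <- utils::combn(n, na, simplify = FALSE)
      lv <- names(tab)
      return(lapply(idx, function(i) {
        lab <- rep(lv[2L], n); lab[i] <- lv[1L]; lab
      }))
    }
  } else {
    total <- factorial(n) / prod(factorial(tab))
    if (total <= n_perm) {
      ## enumerate via permutations of positions, dropping duplicates
      perms <- permuteVector(glab)
      return(perms[!duplicated(vapply(perms, paste, character(1),
                                      collapse = "\r"))])
    }
  }
  withSeed(seed, lapply(seq_len(n_perm), function(i) sample(glab)))
}

## All permutations of a vector (recursive; used only for small n)
permuteVector <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n))
    out <- c(out, lapply(permuteVector(x[-i]), function(p) c(x[i], p)))
  out
}

#' Fisher-exact term enrichment with BH correction
#'
#' For each annotation term, the one-sided (enrichment) Fisher exact test on
#' the 2 x 2 table (in-term/not x significant/not) against the background —
#' the p-value is the upper hypergeometric tail, computed with
#' [stats::phyper()] — plus Benjamini-Hochberg adjustment across terms, the
#' sample odds ratio, and an enrichment z-score (observed minus expected
#' overlap in hypergeometric s.d. units).
#'
#' @param significant character vector, a subset of `background`.
#' @param background character vector of all tested proteins.
#' @param terms named list: term id -> member proteins (e.g. from
#'   [readGMT()]).
#' @param q_cutoff flag terms with BH-adjusted q at or below this value.
#' @return data.frame: `term`, `k` (significant in term), `K` (background in
#'   term), `n` (significant), `N` (background), `odds_ratio`, `z`,
#'   `p`, `q`, `enriched`. Terms without background overlap are skipped
#'   with a warning.
#' @export
fisherEnrichment <- function(significant, background, terms,
                             q_cutoff = 0.05) {
  significant <- unique(significant)
  background <- unique(background)
  if (!all(significant %in% background))
    stop("significant set must be a subset of the background")
  N <- length(background)
  n <- length(significant)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), background)
    K <- length(members)
    if (K == 0L) {
      warning("term ", tm, " has no background overlap; skipped")
      return(NULL)
    }
    k <- length(intersect(members, significant))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.xmin)
    exp_k <- n * K / N
    var_k <- n * (K / N) * (1 - K / N) * (N - n) / max(N - 1, 1)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               odds_ratio = or,
               z = if (var_k > 0) (k - exp_k) / sqrt(var_k) else 0,
               p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      z = numeric(), p = numeric(), q = numeric(),
                      enriched = logical()))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= q_cutoff
  rownames(out) <- NULL
  out
}

#' Row z-scoring
#'
#' Standardizes each row to mean 0, s.d. 1 (n-1 denominator). Constant rows
#' are rejected.
#'
#' @param m numeric matrix or complete [ProteinMatrix-class].
#' @return matrix of the same shape.
#' @export
zscoreRows <- function(m) {
  v <- if (is(m, "ProteinMatrix")) intensities(m) else as.matrix(m)
  if (anyNA(v)) stop("matrix contains missing values")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant row(s): ",
         paste(utils::head(rownames(v)[sds == 0]), collapse = ", "))
  t(scale(t(v)))[, , drop = FALSE]
}
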