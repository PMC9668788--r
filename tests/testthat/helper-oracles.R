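# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive O(n^2) set arithmetic, never the package's
# own labelling/matching code paths.

# Union-find connected components over the foreground of a small 3D logical
# array; labels ordered by each component's minimum linear index.
bruteCC <- function(m, connectivity) {
    d <- dim(m)
    idx <- which(m)
    lab <- array(0L, dim = d)
    if (length(idx) == 0) return(list(labels = lab, k = 0L))
    ai <- arrayInd(idx, d)
    n <- length(idx)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
            dd <- abs(ai[a, ] - ai[b, ])
            if (any(dd > 1)) next
            s <- sum(dd)
            ok <- if (connectivity == 6) s == 1
                  else if (connectivity == 18) s >= 1 && s <= 2
                  else s >= 1
            if (ok) {
                ra <- find(a); rb <- find(b)
                if (ra != rb) parent[rb] <- ra
            }
        }
    }
    root <- vapply(seq_len(n), find, integer(1))
    # order components by minimum linear index of their members
    comp_min <- tapply(idx, root, min)
    ord <- order(comp_min)
    relabel <- integer(max(root))
    relabel[as.integer(names(comp_min))[ord]] <- seq_along(ord)
    lab[idx] <- relabel[root]
    list(labels = lab, k = length(ord))
}

# Exhaustive voxel-set lesion matching: overlap fractions against a labelled
# GT, detections at tau, and FP clusters of pred (components disjoint from
# the GT foreground), all via plain set arithmetic on voxel indices.
bruteMatch <- function(gtlab, pred, tau, connectivity) {
    labs <- sort(unique(gtlab[gtlab > 0]))
    frac <- vapply(labs, function(l) {
        les <- which(gtlab == l)
        length(intersect(les, which(pred))) / length(les)
    }, numeric(1))
    cc <- bruteCC(pred, connectivity)
    fp <- 0L
    gtfg <- which(gtlab > 0)
    for (l in seq_len(cc$k)) {
        if (length(intersect(which(cc$labels == l), gtfg)) == 0)
            fp <- fp + 1L
    }
    list(labels = labs, frac = frac, detected = frac >= tau, fp = fp,
         ncomp = cc$k)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (n <= ~16; no zeros, no tied absolute values).
enumSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    total <- 2^n
    vs <- numeric(total)
    for (m in 0:(total - 1)) {
        bits <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
        vs[m + 1] <- sum(r[bits])
    }
    p_le <- mean(vs <= v_obs)
    p_ge <- mean(vs >= v_obs)
    min(1, 2 * min(p_le, p_ge))
}

# Permutation-test p-value for the two-group log-rank statistic: reshuffle
# group labels, recompute the chi-square statistic with survival::survdiff.
permLogrankP <- function(timeA, eventA, timeB, eventB, nperm = 2000,
                         seed = 42) {
    time <- c(timeA, timeB)
    event <- c(eventA, eventB)
    nA <- length(timeA)
    obs <- survival::survdiff(
        survival::Surv(time, event) ~ rep(c(0, 1), c(nA, length(timeB))))$chisq
    set.seed(seed)
    ge <- 0L
    for (i in seq_len(nperm)) {
        g <- sample(rep(c(0, 1), c(nA, length(timeB))))
        st <- survival::survdiff(survival::Surv(time, event) ~ g)$chisq
        if (st >= obs - 1e-12) ge <- ge + 1L
    }
    (ge + 1) / (nperm + 1)
}

# Small random binary mask with controlled foreground density.
randomMask <- function(dims, p, seed) {
    set.seed(seed)
    array(runif(prod(dims)) < p, dim = dims)
}

# A compact phantom configuration for fast cohort-level tests. Same physics
# and site mix as the full-size default, on a reduced field of view.
smallPhantom <- function(...) {
    phantomConfig(shape = c(48, 48, 128), ...)
}
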