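# Independent oracles: deliberately naive re-implementations used to check
# the package's optimized/structured paths. They share no code with R/.

# Sum-above-threshold by explicit double loop over pixels (column-major so
# the accumulation order matches R storage; summed at the end for identical
# floating-point semantics).
naive_sint <- function(values, k) {
  passing <- numeric(0)
  for (j in seq_len(ncol(values))) {
    for (i in seq_len(nrow(values))) {
      if (values[i, j] > k) passing <- c(passing, values[i, j])
    }
  }
  sum(passing)
}

# Connected components by label propagation to a fixpoint (no flood fill).
oracle_n_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!mask] <- 0L
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (connectivity == 4L && abs(di) + abs(dj) == 2L) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj] &&
            lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(lab[mask]))
}

# Brute-force one-site fit: profile Bmax analytically over a log-spaced Kd
# grid (for fixed Kd the model is linear in Bmax).
grid_fit_oracle <- function(x, y, n_grid = 100L) {
  pos <- x[x > 0]
  kd_grid <- exp(seq(log(min(pos) / 100), log(max(pos) * 100), length.out = n_grid))
  best <- list(rss = Inf)
  for (kd in kd_grid) {
    u <- x / (x + kd)
    bmax <- sum(y * u) / sum(u^2)
    rss <- sum((y - bmax * u)^2)
    if (rss < best$rss) best <- list(Kd = kd, Bmax = bmax, rss = rss)
  }
  best
}

# All permutations of seq_len(n) grown iteratively by insertion.
oracle_permutations <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(0:(k - 1L), function(pos) append(p, k, after = pos))
    }), recursive = FALSE)
  }
  perms
}

# Exact two-sided Spearman permutation p-value by full enumeration.
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  rhos <- vapply(oracle_permutations(length(y)),
                 function(p) stats::cor(rx, ry[p]), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# Classify one germline/mature codon pair via Biostrings translation
# (independent of the package's codon-table lookup path).
oracle_codon_class <- function(gcod, mcod) {
  tr <- function(cod) as.character(Biostrings::translate(Biostrings::DNAString(cod)))
  ndiff <- sum(strsplit(gcod, "")[[1]] != strsplit(mcod, "")[[1]])
  if (ndiff == 0L) return("none")
  if (identical(tr(gcod), tr(mcod))) "silent" else "replacement"
}

# Full per-sequence R/S count by per-codon translation enumeration
# (single-mutation codons only; used on N-free fixtures).
oracle_count_rs <- function(germline, mature) {
  n_codons <- nchar(germline) %/% 3L
  repl <- 0L; sil <- 0L; total <- 0L
  for (i in seq_len(n_codons)) {
    g <- substr(germline, 3 * i - 2, 3 * i)
    m <- substr(mature, 3 * i - 2, 3 * i)
    nd <- sum(strsplit(g, "")[[1]] != strsplit(m, "")[[1]])
    total <- total + nd
    if (nd == 0L) next
    cls <- oracle_codon_class(g, m)
    if (cls == "silent") sil <- sil + nd else repl <- repl + nd
  }
  c(total = total, replacement = repl, silent = sil)
}

# Mutual-blocking components by boolean reachability (matrix closure).
oracle_blocking_groups <- function(m, threshold = 50) {
  ids <- rownames(m)
  self_ok <- diag(m) >= threshold
  blockers <- ids[self_ok]
  b <- m[blockers, blockers, drop = FALSE]
  adj <- (b >= threshold) & (t(b) >= threshold)
  diag(adj) <- TRUE
  reach <- adj
  for (step in seq_along(blockers)) {
    reach <- (reach %*% adj) > 0
  }
  comp_of <- apply(reach, 1L, function(r) paste(sort(blockers[r]), collapse = "|"))
  groups <- lapply(unique(comp_of), function(key) strsplit(key, "|", fixed = TRUE)[[1]])
  list(groups = groups[order(vapply(groups, `[`, character(1), 1L))],
       non_blockers = sort(ids[!self_ok]))
}

# Exact median-difference p-value by bitmask enumeration of assignments.
oracle_median_perm_p <- function(vals, groups) {
  levs <- sort(unique(groups))
  n <- length(vals); n1 <- sum(groups == levs[1])
  obs <- abs(median(vals[groups == levs[1]]) - median(vals[groups == levs[2]]))
  hits <- 0L; count <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) != n1) next
    count <- count + 1L
    stat <- abs(median(vals[sel]) - median(vals[-sel]))
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  c(p = hits / count, n_assignments = count)
}
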