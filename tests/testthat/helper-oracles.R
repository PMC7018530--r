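# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: exhaustive enumeration and closed forms, never the
# dynamic-programming / greedy code paths they check.

# toy scoring scheme over a 3-letter alphabet: match 2, mismatch -1,
# gap of length g costs 3 + g
toy_scheme <- function() {
  m <- matrix(-1L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(m) <- 2L
  scoring_scheme(m, gap_open = -3L, gap_extend = -1L, lambda = 1, k = 1,
                 matrix_name = "toy")
}

# Brute-force optimal local alignment score: enumerate every chain of aligned
# column pairs (strictly increasing in both sequences); residues skipped
# between consecutive columns are charged as affine gaps. Valid whenever the
# worst substitution score is no worse than one gap-extension step, which
# holds for the toy scheme.
brute_local_score <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sub <- scheme$substitution
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  gapcost <- function(g) if (g == 0) 0 else go + ge * g
  n <- length(av)
  m <- length(bv)
  best <- 0
  for (k in seq_len(min(n, m))) {
    rows <- combn(n, k)
    cols <- combn(m, k)
    for (ri in seq_len(ncol(rows))) {
      I <- rows[, ri]
      row_sub <- sub[av[I], , drop = FALSE]
      for (ci in seq_len(ncol(cols))) {
        J <- cols[, ci]
        sc <- sum(row_sub[cbind(seq_len(k), match(bv[J], colnames(sub)))])
        if (k > 1) {
          sc <- sc + sum(vapply(diff(I) - 1L, gapcost, numeric(1))) +
            sum(vapply(diff(J) - 1L, gapcost, numeric(1)))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Brute-force minimum spanning tree total distance on a connected graph:
# enumerate all (n-1)-edge subsets and keep the cheapest spanning one.
brute_mst_distance <- function(nodes, edges) {
  n <- length(nodes)
  if (n <= 1 || !nrow(edges)) return(0)
  best <- Inf
  sel_list <- combn(nrow(edges), n - 1, simplify = FALSE)
  for (sel in sel_list) {
    sub <- edges[sel, , drop = FALSE]
    g <- igraph::graph_from_data_frame(sub[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = nodes))
    if (igraph::is_connected(g)) best <- min(best, sum(sub$distance))
  }
  best
}

# hard-coded orderings of up to three differing codon positions
perm_table <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Brute-force Nei-Gojobori pathway averaging over explicitly tabulated
# orderings of the differing positions.
brute_syn_nonsyn <- function(ca, cb) {
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0) return(c(syn = 0, nonsyn = 0))
  orders <- perm_table[[d]]
  res <- matrix(0, nrow(orders), 3)
  for (o in seq_len(nrow(orders))) {
    cur <- a
    for (p in pos[orders[o, ]]) {
      prev_aa <- code[[paste(cur, collapse = "")]]
      cur[p] <- b[p]
      new_aa <- code[[paste(cur, collapse = "")]]
      if (new_aa == "*") res[o, 3] <- 1
      if (new_aa == prev_aa) res[o, 1] <- res[o, 1] + 1
      else res[o, 2] <- res[o, 2] + 1
    }
  }
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(syn = mean(res[ok, 1]), nonsyn = mean(res[ok, 2]))
}

# closed-form simple OLS via normal equations
ols_normal_equations <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# all sequences of a given length over an alphabet
all_kmers <- function(alphabet, k) {
  grids <- do.call(expand.grid, rep(list(alphabet), k))
  apply(grids, 1, paste, collapse = "")
}

random_aa_string <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
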