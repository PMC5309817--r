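# Shared fixtures and independent oracles.

# Tiny abundance table: `values` is taxa x samples; all samples one stage
# unless sample_meta is supplied.
make_table <- function(values, stage = "recent", subgroup = NULL,
                       main_group = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("t", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (is.null(subgroup)) subgroup <- rep("g1", nrow(values))
  if (is.null(main_group)) main_group <- subgroup
  abundance_table(
    values,
    taxon_meta = data.frame(taxon_id = rownames(values),
                            subgroup = subgroup, main_group = main_group,
                            trophic_function = "unknown",
                            stringsAsFactors = FALSE),
    sample_meta = data.frame(sample_id = colnames(values), site = "S1",
                             subplot = seq_len(ncol(values)), stage = stage,
                             stringsAsFactors = FALSE)
  )
}

# Independent Spearman oracle: average ranks, then Pearson from first
# principles (no call to cor()).
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (length(unique(rx)) == 1 || length(unique(ry)) == 1) return(NA_real_)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_spearman_matrix <- function(values) {
  n <- nrow(values)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(values),
                                                rownames(values)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- oracle_spearman(values[i, ], values[j, ])
    }
  }
  out
}

# Fixture with exactly one perfectly rank-correlated pair among 4 taxa over
# 5 samples; all other pairwise Spearman correlations are <= 0.8.
one_edge_table <- function(stage = "recent") {
  v <- rbind(
    t1 = c(1, 2, 3, 4, 5),
    t2 = c(2, 4, 6, 8, 10),
    t3 = c(5, 3, 1, 4, 2),
    t4 = c(2, 1, 4, 3, 5)
  )
  make_table(v, stage = stage, subgroup = c("A", "A", "B", "B"))
}

stage_connectances <- function(tab, ...) {
  vapply(c("recent", "mid", "long"),
         function(st) stage_network(tab, st, ...)$summary$connectance_pct,
         numeric(1))
}
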