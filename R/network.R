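#' Spearman rank correlation matrix over taxa
#'
#' Computes all pairwise Spearman rank correlations between taxa across the
#' table's samples, with average ranks for ties (the convention of
#' `stats::cor`). A taxon whose abundances have zero rank variance (constant
#' across samples) yields `NA` in every entry involving it, including its
#' diagonal — the explicit undefined marker, never silent NaN propagation.
#'
#' @param x an [abundance_table()] (typically one stage after
#'   [filter_single_occurrence()]).
#' @return an object of class `spearman_matrix`: list with `rho` (symmetric
#'   taxon x taxon matrix, `NA` where undefined) and `n_samples`.
#' @export
spearman_matrix <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  v <- x$values
  if (ncol(v) < 2) stop("need >= 2 samples", call. = FALSE)
  if (nrow(v) < 2) stop("need >= 2 taxa", call. = FALSE)
  rho <- suppressWarnings(stats::cor(t(v), method = "spearman"))
  constant <- apply(v, 1, function(r) length(unique(r)) == 1)
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho)[!constant] <- 1
  structure(list(rho = rho, n_samples = ncol(v)), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat(sprintf("spearman_matrix: %d taxa over %d samples (%d undefined pairs)\n",
              nrow(x$rho), x$n_samples,
              sum(is.na(x$rho[upper.tri(x$rho)]))))
  invisible(x)
}

#' Extract strong positive correlation edges
#'
#' Keeps the taxon pairs whose Spearman correlation exceeds the threshold.
#' Only positive correlations form edges; undefined (NA) correlations are
#' never edges. The default is strict `rho > tau` — the convention of the
#' connectance arithmetic — with `strict = FALSE` switching to `rho >= tau`
#' (the visualization convention); with continuous abundances the two differ
#' only at exact ties with `tau`.
#'
#' @param m a [spearman_matrix()].
#' @param tau correlation threshold in (0, 1); default 0.9.
#' @param strict logical; `TRUE` keeps `rho > tau`, `FALSE` keeps
#'   `rho >= tau`.
#' @return an object of class `edge_set`: data.frame with columns `a`, `b`
#'   (canonically `a` before `b` in matrix order) and `rho`, with attributes
#'   `tau`, `strict` and `taxa` (all taxa of the matrix).
#' @export
build_edges <- function(m, tau = 0.9, strict = TRUE) {
  stopifnot(inherits(m, "spearman_matrix"))
  if (!(tau > 0 && tau < 1)) stop("tau must be in (0, 1)", call. = FALSE)
  rho <- m$rho
  ut <- upper.tri(rho)
  hit <- ut & !is.na(rho) & (if (strict) rho > tau else rho >= tau)
  idx <- which(hit, arr.ind = TRUE)
  edges <- data.frame(
    a = rownames(rho)[idx[, 1]],
    b = colnames(rho)[idx[, 2]],
    rho = rho[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(match(edges$a, rownames(rho)),
                       match(edges$b, rownames(rho))), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("edge_set", "data.frame"),
            tau = tau, strict = strict, taxa = rownames(rho))
}

#' Percentage connectance
#'
#' Realized strong correlations as a percentage of all counted taxon pairs:
#' `100 * n_strong / n_possible`.
#'
#' @param n_strong number of super-threshold correlations.
#' @param n_possible number of counted taxon pairs.
#' @return connectance percentage in \[0, 100\].
#' @export
#' @examples
#' connectance(10961, 1749816)  # 0.626 after rounding to 3 decimals
connectance <- function(n_strong, n_possible) {
  if (any(n_possible <= 0)) stop("n_possible must be > 0", call. = FALSE)
  if (any(n_strong < 0) || any(n_strong > n_possible)) {
    stop("need 0 <= n_strong <= n_possible", call. = FALSE)
  }
  100 * n_strong / n_possible
}

#' Count the possible taxon pairs under a denominator policy
#'
#' `all_pairs` counts every unordered pair among the N retained taxa,
#' `N(N-1)/2`; `between_only` counts only pairs spanning two different
#' groups, `sum_{a<b} |a|*|b|` — within-group pairs are then excluded from
#' both numerator and denominator.
#'
#' @param group_sizes named integer vector of taxa per group (or a character
#'   vector of group labels, one per taxon, which is tabulated).
#' @param policy `"all_pairs"` or `"between_only"`.
#' @return integer pair count.
#' @export
count_possible <- function(group_sizes, policy = c("all_pairs", "between_only")) {
  policy <- match.arg(policy)
  if (is.character(group_sizes) || is.factor(group_sizes)) {
    group_sizes <- table(group_sizes)
  }
  group_sizes <- as.numeric(group_sizes)
  if (length(group_sizes) == 0 || any(group_sizes <= 0)) {
    stop("groups must be non-empty", call. = FALSE)
  }
  n <- sum(group_sizes)
  if (policy == "all_pairs") {
    n * (n - 1) / 2
  } else {
    (n^2 - sum(group_sizes^2)) / 2
  }
}

#' Group-level interaction strengths
#'
#' For each unordered pair of functional groups, the interaction strength is
#' the number of strong edges between the two groups divided by the number
#' of possible pairs `|a| * |b|`. Within-group strengths (denominator
#' `|a|(|a|-1)/2`) are computed as well but flagged `displayed = FALSE`,
#' matching the convention that only between-group links are drawn.
#'
#' @param edges an [edge_set][build_edges()].
#' @param groups named character vector mapping every taxon of the network
#'   to its group label.
#' @return data.frame with columns `group_a`, `group_b`, `n_strong`,
#'   `n_possible`, `strength`, `displayed`.
#' @export
interaction_strengths <- function(edges, groups) {
  taxa <- attr(edges, "taxa")
  unmapped <- setdiff(taxa, names(groups))
  if (length(unmapped) > 0) {
    stop("taxa without a group: ", paste(utils::head(unmapped, 5),
                                         collapse = ", "), call. = FALSE)
  }
  sizes <- table(factor(groups[taxa]))
  labs <- names(sizes)
  pairs <- expand.grid(i = seq_along(labs), j = seq_along(labs))
  pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
  ga <- unname(groups[edges$a])
  gb <- unname(groups[edges$b])
  key <- paste(pmin(ga, gb), pmax(ga, gb), sep = "\r")
  out <- data.frame(
    group_a = labs[pairs$i],
    group_b = labs[pairs$j],
    stringsAsFactors = FALSE
  )
  ka <- pmin(out$group_a, out$group_b)
  kb <- pmax(out$group_a, out$group_b)
  out$n_strong <- as.integer(
    vapply(paste(ka, kb, sep = "\r"), function(k) sum(key == k), numeric(1))
  )
  within <- out$group_a == out$group_b
  na <- as.numeric(sizes[out$group_a])
  nb <- as.numeric(sizes[out$group_b])
  out$n_possible <- ifelse(within, na * (na - 1) / 2, na * nb)
  out$strength <- ifelse(out$n_possible > 0,
                         out$n_strong / out$n_possible, NA_real_)
  out$displayed <- !within
  rownames(out) <- NULL
  out
}

#' Per-stage co-occurrence network and tightening statistics
#'
#' The full per-stage pipeline: subset to the stage's samples, drop
#' single-sample occurrences, compute the Spearman matrix, threshold it into
#' strong positive edges, and summarize connectance plus group-level
#' interaction strengths at both the subgroup and main-group level. Fully
#' deterministic and invariant under sample reordering and any strictly
#' monotone per-taxon abundance transform.
#'
#' @param x an [abundance_table()] covering one or more stages.
#' @param stage which succession stage to analyse.
#' @param tau correlation threshold (default 0.9).
#' @param policy denominator policy, see [count_possible()]; `all_pairs`
#'   (default) counts every retained taxon pair, `between_only` restricts
#'   numerator and denominator to pairs spanning two subgroups.
#' @param binary if `TRUE`, run on presence-absence data ([binarize()]).
#' @param strict strict (`>`) or inclusive (`>=`) thresholding.
#' @param exclude_groups main-group labels dropped before analysis (e.g.
#'   protists counted in too few replicates); default none.
#' @return an object of class `stage_network`: list with `stage`, `policy`,
#'   `tau`, `binary`, the filtered `table`, `correlation`
#'   ([spearman_matrix()]), `edges` ([build_edges()]), `summary` (one-row
#'   data.frame: stage, n_taxa, n_strong, n_possible, connectance_pct,
#'   policy, tau) and `interactions` (list with `subgroup` and `main_group`
#'   [interaction_strengths()] tables).
#' @export
stage_network <- function(x, stage, tau = 0.9,
                          policy = c("all_pairs", "between_only"),
                          binary = FALSE, strict = TRUE,
                          exclude_groups = character()) {
  policy <- match.arg(policy)
  stopifnot(inherits(x, "abundance_table"))
  if (length(exclude_groups) > 0) {
    keep <- !(x$taxon_meta$main_group %in% exclude_groups)
    x$values <- x$values[keep, , drop = FALSE]
    x$taxon_meta <- x$taxon_meta[keep, , drop = FALSE]
  }
  if (binary) x <- binarize(x)
  tab <- filter_single_occurrence(x, stage)
  m <- spearman_matrix(tab)
  edges <- build_edges(m, tau = tau, strict = strict)
  sub_map <- stats::setNames(tab$taxon_meta$subgroup, tab$taxon_meta$taxon_id)
  main_map <- stats::setNames(tab$taxon_meta$main_group,
                              tab$taxon_meta$taxon_id)
  is_sub <- interaction_strengths(edges, sub_map)
  is_main <- interaction_strengths(edges, main_map)
  if (policy == "all_pairs") {
    n_strong <- nrow(edges)
  } else {
    between <- sub_map[edges$a] != sub_map[edges$b]
    n_strong <- sum(between)
  }
  n_possible <- count_possible(unname(sub_map), policy)
  summary <- data.frame(
    stage = stage,
    n_taxa = nrow(tab$values),
    n_strong = as.integer(n_strong),
    n_possible = as.integer(n_possible),
    connectance_pct = connectance(n_strong, n_possible),
    policy = policy,
    tau = tau,
    binary = binary,
    stringsAsFactors = FALSE
  )
  structure(
    list(stage = stage, tau = tau, policy = policy, binary = binary,
         table = tab, correlation = m, edges = edges, summary = summary,
         interactions = list(subgroup = is_sub, main_group = is_main)),
    class = "stage_network"
  )
}

#' @export
print.stage_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("stage_network [%s]%s: %d taxa, %d strong / %d possible pairs\n",
              x$stage, if (x$binary) " (presence-absence)" else "",
              s$n_taxa, s$n_strong, s$n_possible))
  cat(sprintf("  connectance = %.3f%% (tau = %g, policy = %s)\n",
              s$connectance_pct, x$tau, x$policy))
  invisible(x)
}

#' @export
summary.stage_network <- function(object, ...) object$summary

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over the positive abundance proportions, natural
#' logarithm — the evenness statistic used for the plant communities.
#'
#' @param abundances non-negative numeric vector with at least one positive
#'   entry.
#' @return Shannon H (nats).
#' @export
#' @examples
#' shannon_index(rep(1, 4))  # log(4)
shannon_index <- function(abundances) {
  if (any(abundances < 0) || any(!is.finite(abundances))) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  p <- abundances[abundances > 0]
  if (length(p) == 0) stop("all abundances are zero", call. = FALSE)
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Export a stage network's edges
#'
#' Writes the strong-edge list for external graph tools: `sif` (Cytoscape
#' simple interaction format, one `a pp b` line per edge), `graphml` (with
#' edge attribute `rho` and node attribute `group`), or `tsv` (columns `a`,
#' `b`, `rho`, `group_a`, `group_b`).
#'
#' @param net a [stage_network()].
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @param group_level `"subgroup"` or `"main_group"` annotation used for
#'   node groups.
#' @return `path`, invisibly.
#' @export
export_edges <- function(net, path, format = c("sif", "graphml", "tsv"),
                         group_level = c("subgroup", "main_group")) {
  format <- match.arg(format)
  group_level <- match.arg(group_level)
  stopifnot(inherits(net, "stage_network"))
  edges <- net$edges
  groups <- stats::setNames(net$table$taxon_meta[[group_level]],
                            net$table$taxon_meta$taxon_id)
  if (format == "sif") {
    writeLines(if (nrow(edges) > 0) paste(edges$a, "pp", edges$b) else
      character(0), path)
  } else if (format == "tsv") {
    out <- data.frame(a = edges$a, b = edges$b, rho = edges$rho,
                      group_a = unname(groups[edges$a]),
                      group_b = unname(groups[edges$b]),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    taxa <- attr(net$edges, "taxa")
    g <- igraph::graph_from_data_frame(
      edges[, c("a", "b", "rho")], directed = FALSE,
      vertices = data.frame(name = taxa, group = unname(groups[taxa]),
                            stringsAsFactors = FALSE)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Strong-correlation counts for a restored-grassland chronosequence
#'
#' The published per-stage counts of strong correlations (Spearman rho >
#' 0.9) and of all possible taxon-pair connections for a three-stage
#' land-abandonment chronosequence, at two aggregation levels (functional
#' subgroups and main species groups). Dividing the counts reproduces the
#' reported connectance percentages and the recent-to-mid "tightening" step.
#'
#' @return data.frame with columns `level`, `stage`, `n_strong`,
#'   `n_possible`.
#' @export
#' @examples
#' counts <- restoration_connectance_counts()
#' round(connectance(counts$n_strong, counts$n_possible), 3)
restoration_connectance_counts <- function() {
  data.frame(
    level = rep(c("subgroup", "main_group"), each = 3),
    stage = rep(c("recent", "mid", "long"), 2),
    n_strong = c(10961, 26571, 19308, 4833, 12621, 9029),
    n_possible = c(1749816, 2239795, 1510742, 822361, 1057646, 786379),
    stringsAsFactors = FALSE
  )
}
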