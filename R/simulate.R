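#' Specification of a synthetic multi-stage community
#'
#' Describes the sampling design and correlation structure of a simulated
#' chronosequence community: 3 succession stages, 3 sites per stage with 3
#' subplots each (9 samples per stage, the classic restoration design),
#' functional subgroups of taxa, a per-stage within-subgroup target Spearman
#' correlation `rho_block`, and an occupancy (detection) probability.
#'
#' Taxa within a subgroup share a per-sample latent Gaussian factor with
#' weight `2 * sin(pi * rho_block / 6)` — the Pearson correlation that a
#' bivariate Gaussian copula needs for a population Spearman correlation of
#' `rho_block`. Abundances are a monotone (lognormal) transform of the
#' latent, so the Spearman target survives; a taxon is absent from a sample
#' when its latent falls below the occupancy quantile, so presence-absence
#' patterns retain the block correlation too (absences attenuate the
#' realized Spearman slightly below the target).
#'
#' @param groups data.frame with columns `subgroup`, `main_group`,
#'   `trophic_function`, `n_taxa`; default: a 13-subgroup, 59-taxon soil
#'   community (bacteria, fungi, AMF, nematode feeding guilds, mites,
#'   collembola, plants).
#' @param rho_block numeric vector, one target Spearman correlation in
#'   \[0, 1\] per stage; default `c(0.3, 0.7, 0.7)` (a recent-to-mid
#'   tightening step, then a plateau).
#' @param sites_per_stage,subplots_per_site design constants (default 3
#'   and 3).
#' @param occupancy probability a taxon is detected in a sample (default
#'   0.9).
#' @param stages stage labels, default `c("recent", "mid", "long")`.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(groups = default_community_groups(),
                           rho_block = c(0.3, 0.7, 0.7),
                           sites_per_stage = 3, subplots_per_site = 3,
                           occupancy = 0.9,
                           stages = stage_levels()) {
  if (any(rho_block < 0) || any(rho_block > 1)) {
    stop("rho_block must be in [0, 1]", call. = FALSE)
  }
  if (length(rho_block) != length(stages)) {
    stop("need one rho_block per stage", call. = FALSE)
  }
  if (occupancy <= 0 || occupancy > 1) {
    stop("occupancy must be in (0, 1]", call. = FALSE)
  }
  need <- c("subgroup", "main_group", "trophic_function", "n_taxa")
  if (!all(need %in% names(groups))) {
    stop("groups needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (sites_per_stage * subplots_per_site < 2) {
    stop("need >= 2 samples per stage", call. = FALSE)
  }
  structure(list(groups = groups, rho_block = rho_block,
                 sites_per_stage = sites_per_stage,
                 subplots_per_site = subplots_per_site,
                 occupancy = occupancy, stages = stages),
            class = "community_spec")
}

#' @rdname community_spec
#' @export
default_community_groups <- function() {
  data.frame(
    subgroup = c("bacteria_copiotroph", "bacteria_oligotroph",
                 "actinomycetes", "fungi_saprotrophic", "fungi_other",
                 "AMF", "nematodes_bacterivorous", "nematodes_fungivorous",
                 "nematodes_rootfeeding", "mites_fungivorous",
                 "mites_predaceous", "collembola_fungivorous", "plants"),
    main_group = c("bacteria", "bacteria", "bacteria", "fungi", "fungi",
                   "AMF", "nematodes", "nematodes", "nematodes", "mites",
                   "mites", "collembola", "plants"),
    trophic_function = c("saprotrophic", "saprotrophic", "saprotrophic",
                         "saprotrophic", "saprotrophic", "symbiotic",
                         "bacterivorous", "fungivorous", "root-feeding",
                         "fungivorous", "predaceous", "fungivorous",
                         "primary-producer"),
    n_taxa = c(6, 6, 6, 5, 5, 6, 4, 4, 4, 3, 3, 3, 4),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic abundance table
#'
#' Draws a community according to a [community_spec()]: per stage and
#' sample, each subgroup gets a shared latent factor; each taxon mixes that
#' factor with independent noise, is zeroed when its latent falls below the
#' occupancy quantile, and otherwise reports a lognormal abundance.
#' Deterministic given `seed`.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return an [abundance_table()]; synthetic site codes are
#'   `"<stage-initial><site>"` (e.g. `R1`), sample ids
#'   `"<site>_p<subplot>"`.
#' @export
generate_abundance <- function(spec = community_spec(), seed = 1) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(as.integer(seed))
  groups <- spec$groups
  taxa <- data.frame(
    taxon_id = unlist(mapply(function(g, n) paste0(g, "_t", seq_len(n)),
                             groups$subgroup, groups$n_taxa,
                             SIMPLIFY = FALSE)),
    subgroup = rep(groups$subgroup, groups$n_taxa),
    main_group = rep(groups$main_group, groups$n_taxa),
    trophic_function = rep(groups$trophic_function, groups$n_taxa),
    stringsAsFactors = FALSE
  )
  rownames(taxa) <- NULL
  n_taxa <- nrow(taxa)
  n_samp <- spec$sites_per_stage * spec$subplots_per_site
  cut <- stats::qnorm(1 - spec$occupancy)
  blocks <- split(seq_len(n_taxa), taxa$subgroup)
  all_values <- NULL
  sample_meta <- NULL
  for (si in seq_along(spec$stages)) {
    stage <- spec$stages[si]
    # Pearson weight giving target Spearman under the Gaussian copula
    w <- 2 * sin(pi * spec$rho_block[si] / 6)
    z <- matrix(NA_real_, n_taxa, n_samp)
    for (b in blocks) {
      latent <- stats::rnorm(n_samp)
      eps <- matrix(stats::rnorm(length(b) * n_samp), length(b), n_samp)
      z[b, ] <- sqrt(w) * rep(latent, each = length(b)) +
        sqrt(1 - w) * eps
    }
    v <- ifelse(z < cut, 0, round(100 * exp(z), 3))
    site <- paste0(toupper(substr(stage, 1, 1)),
                   rep(seq_len(spec$sites_per_stage),
                       each = spec$subplots_per_site))
    subplot <- rep(seq_len(spec$subplots_per_site), spec$sites_per_stage)
    ids <- paste0(site, "_p", subplot)
    colnames(v) <- ids
    all_values <- cbind(all_values, v)
    sample_meta <- rbind(sample_meta,
                         data.frame(sample_id = ids, site = site,
                                    subplot = subplot, stage = stage,
                                    stringsAsFactors = FALSE))
  }
  rownames(all_values) <- taxa$taxon_id
  abundance_table(all_values, taxa, sample_meta)
}

#' Specification of a synthetic pulse-chase tracer experiment
#'
#' Describes a dual-label pulse-chase with known ground truth: the total
#' excess 13C arriving in the roots (atom percent units), the fraction of
#' that root label transferred to each microbial pool (1-day time point)
#' and to each consumer/predator group (1-week and 2-week time points),
#' multiplicative lognormal measurement noise, and the replicate count.
#'
#' @param root_excess excess atom percent 13C in roots (default 2).
#' @param transfer named numeric vector of per-pool transfer fractions of
#'   the root label; defaults emulate a community where fungi take about
#'   half the carbon: bacteria 0.08, fungi 0.10, AMF 0.02 at 1 day, plus
#'   small consumer (1w) and predator (2w) transfers.
#' @param time_point named character vector assigning each pool its
#'   reporting time point; defaults: microbes at `1d`, consumers at `1w`,
#'   predators at `2w`.
#' @param sigma multiplicative lognormal noise on the label increment
#'   (sdlog; 0 = noiseless), default 0.05.
#' @param n_replicates replicate cores per treatment, default 9.
#' @param baseline_delta natural-abundance delta 13C of unlabelled material
#'   (permil), default -27.
#' @return list of class `tracer_spec`.
#' @export
tracer_spec <- function(root_excess = 2,
                        transfer = c(bacteria = 0.08, fungi = 0.10,
                                     AMF = 0.02,
                                     nematodes_bacterivorous = 0.010,
                                     nematodes_fungivorous = 0.012,
                                     collembola_fungivorous = 0.008,
                                     mites_predaceous = 0.004),
                        time_point = c(bacteria = "1d", fungi = "1d",
                                       AMF = "1d",
                                       nematodes_bacterivorous = "1w",
                                       nematodes_fungivorous = "1w",
                                       collembola_fungivorous = "1w",
                                       mites_predaceous = "2w"),
                        sigma = 0.05, n_replicates = 9,
                        baseline_delta = -27) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (any(transfer < 0)) {
    stop("transfer fractions must be >= 0", call. = FALSE)
  }
  if (root_excess <= 0) stop("root_excess must be > 0", call. = FALSE)
  if (!all(names(transfer) %in% names(time_point))) {
    stop("every pool needs a time point", call. = FALSE)
  }
  structure(list(root_excess = root_excess, transfer = transfer,
                 time_point = time_point, sigma = sigma,
                 n_replicates = n_replicates,
                 baseline_delta = baseline_delta),
            class = "tracer_spec")
}

#' Generate a synthetic tracer measurement table
#'
#' Emits labelled and control atom-percent 13C measurements per compartment
#' and time point. Controls carry the natural-abundance baseline; labelled
#' samples add the true label increment times a lognormal noise factor
#' (`exp(rnorm(1, 0, sigma))`, mean-corrected so the expected increment
#' equals the truth), so in the noiseless case excess recovers the truth
#' exactly and control compartments always have excess 0.
#'
#' @param spec a [tracer_spec()].
#' @param seed integer seed.
#' @return list with `measurements` (data.frame in [read_isotope()] layout
#'   plus a `replicate` column) and `truth` (list: `root_excess`,
#'   `pool_excess`, per-time-point channel `fractions`).
#' @export
generate_tracer <- function(spec = tracer_spec(), seed = 1) {
  stopifnot(inherits(spec, "tracer_spec"))
  set.seed(as.integer(seed))
  base_ap <- delta_to_atom_percent(spec$baseline_delta,
                                   reference_ratios()$C)
  pools <- names(spec$transfer)
  pool_excess <- spec$root_excess * spec$transfer
  comps <- data.frame(
    compartment = c("roots", pools),
    time_point = c("1d", unname(spec$time_point[pools])),
    increment = c(spec$root_excess, unname(pool_excess)),
    stringsAsFactors = FALSE
  )
  noise <- function(n) {
    if (spec$sigma == 0) rep(1, n)
    else exp(stats::rnorm(n, -spec$sigma^2 / 2, spec$sigma))
  }
  rows <- lapply(seq_len(nrow(comps)), function(i) {
    n <- spec$n_replicates
    lab <- pmin(base_ap + comps$increment[i] * noise(n), 100)
    rbind(
      data.frame(compartment = comps$compartment[i], element = "C",
                 time_point = comps$time_point[i], treatment = "labelled",
                 replicate = seq_len(n), value = lab,
                 value_kind = "atom_percent", stringsAsFactors = FALSE),
      data.frame(compartment = comps$compartment[i], element = "C",
                 time_point = comps$time_point[i], treatment = "control",
                 replicate = seq_len(n), value = rep(base_ap, n),
                 value_kind = "atom_percent", stringsAsFactors = FALSE)
    )
  })
  measurements <- do.call(rbind, rows)
  fractions <- lapply(split(pool_excess, spec$time_point[pools]),
                      function(p) p / sum(p))
  list(measurements = measurements,
       truth = list(root_excess = spec$root_excess,
                    pool_excess = pool_excess,
                    fractions = fractions))
}

#' Recover channel fractions from a tracer measurement table
#'
#' The end-to-end tracer pipeline: compute per-compartment excess atom
#' percent against controls ([summarize_excess()]), take the root
#' compartment as the scaling reference, and partition the remaining
#' compartments of one time point into channel fractions
#' ([channel_partition()]).
#'
#' @param measurements measurement table ([read_isotope()] layout).
#' @param time_point which chase time point to partition (default `"1d"`,
#'   the microbial pools).
#' @param element element, default `"C"`.
#' @param refs reference ratios.
#' @return a [channel_partition()] budget.
#' @export
tracer_budget <- function(measurements, time_point = "1d", element = "C",
                          refs = reference_ratios()) {
  exc <- summarize_excess(measurements, refs = refs)
  root <- exc$excess[exc$compartment == "roots" & exc$element == element]
  if (length(root) != 1 || root <= 0) {
    stop("need exactly one roots compartment with positive excess",
         call. = FALSE)
  }
  sel <- exc$element == element & exc$time_point == time_point &
    exc$compartment != "roots"
  if (!any(sel)) {
    stop("no non-root compartments at time point '", time_point, "'",
         call. = FALSE)
  }
  pool_excess <- stats::setNames(exc$excess[sel], exc$compartment[sel])
  channel_partition(pool_excess, root_excess = root)
}
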