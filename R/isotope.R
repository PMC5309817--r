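#' Isotope reference ratios
#'
#' Heavy/light isotope ratios of the delta-scale reference materials:
#' Vienna Pee Dee Belemnite for 13C/12C and atmospheric N2 for 15N/14N
#' (IAEA-recommended values). Overridable for other reference scales.
#'
#' @param R_VPDB 13C/12C ratio of VPDB.
#' @param R_airN2 15N/14N ratio of air N2.
#' @return named list with `C` and `N` reference ratios.
#' @export
reference_ratios <- function(R_VPDB = 0.0111802, R_airN2 = 0.0036765) {
  if (R_VPDB <= 0 || R_airN2 <= 0) {
    stop("reference ratios must be > 0", call. = FALSE)
  }
  list(C = R_VPDB, N = R_airN2)
}

#' Certified isotope standards
#'
#' Certified delta values (permil) of the reference materials used for
#' IRMS standard-curve calibration: USGS40 and USGS41 (L-glutamic acid),
#' NIST8542 (sucrose, carbon only) and USGS25 (ammonium sulfate, nitrogen
#' only).
#'
#' @return data.frame with columns `name`, `d13C`, `d15N` (`NA` where the
#'   material is not certified for that element).
#' @export
isotope_standards <- function() {
  data.frame(
    name = c("USGS40", "USGS41", "NIST8542", "USGS25"),
    d13C = c(-26.39, 37.63, -10.45, NA),
    d15N = c(-4.52, 47.57, NA, -30.41),
    stringsAsFactors = FALSE
  )
}

#' Elemental-content standards
#'
#' Compounds of known carbon and nitrogen mass fraction used to build the
#' thermal-conductivity-detector standard curve that converts detector
#' signal into micrograms of element.
#'
#' @return data.frame with columns `name`, `pct_C`, `pct_N`.
#' @export
element_standards <- function() {
  data.frame(
    name = c("sulfanilamide", "nicotinamide", "L-aspartic acid"),
    pct_C = c(41.84, 59.01, 36.09),
    pct_N = c(16.27, 22.94, 10.52),
    stringsAsFactors = FALSE
  )
}

#' Delta notation from an isotope ratio, and back
#'
#' `delta = (R_sample / R_ref - 1) * 1000` permil;
#' `ratio_from_delta` is the exact inverse, `R = R_ref * (delta/1000 + 1)`.
#'
#' @param R_sample heavy/light isotope ratio of the sample (> 0).
#' @param R_ref reference ratio (> 0), e.g. `reference_ratios()$C`.
#' @param delta delta value in permil (> -1000).
#' @return delta in permil, or the isotope ratio.
#' @export
delta_from_ratio <- function(R_sample, R_ref) {
  if (any(R_sample <= 0) || any(R_ref <= 0)) {
    stop("isotope ratios must be > 0", call. = FALSE)
  }
  (R_sample / R_ref - 1) * 1000
}

#' @rdname delta_from_ratio
#' @export
ratio_from_delta <- function(delta, R_ref) {
  if (any(delta <= -1000)) stop("delta must be > -1000 permil", call. = FALSE)
  if (any(R_ref <= 0)) stop("reference ratio must be > 0", call. = FALSE)
  R_ref * (delta / 1000 + 1)
}

#' Atom percent of the heavy isotope
#'
#' `atom% = 100 * heavy / (light + heavy)`, the heavy-isotope share of all
#' atoms of the element. The delta route first recovers the ratio against
#' the reference: `R = R_ref * (delta/1000 + 1)`, then
#' `atom% = 100 * R / (1 + R)`.
#'
#' @param heavy heavy-isotope amount (>= 0).
#' @param light light-isotope amount (> 0).
#' @param delta delta value in permil.
#' @param R_ref reference ratio.
#' @param atom_pct atom percent in (0, 100).
#' @return atom percent in \[0, 100\], or the delta value for the inverse.
#' @export
#' @examples
#' delta_to_atom_percent(0, reference_ratios()$C)  # ~1.10566
atom_percent <- function(heavy, light) {
  if (any(light <= 0)) stop("light-isotope amount must be > 0", call. = FALSE)
  if (any(heavy < 0)) stop("heavy-isotope amount must be >= 0", call. = FALSE)
  100 * heavy / (light + heavy)
}

#' @rdname atom_percent
#' @export
delta_to_atom_percent <- function(delta, R_ref) {
  R <- ratio_from_delta(delta, R_ref)
  100 * R / (1 + R)
}

#' @rdname atom_percent
#' @export
atom_percent_to_delta <- function(atom_pct, R_ref) {
  if (any(atom_pct <= 0) || any(atom_pct >= 100)) {
    stop("atom percent must be in (0, 100)", call. = FALSE)
  }
  R <- atom_pct / (100 - atom_pct)
  delta_from_ratio(R, R_ref)
}

#' Fit an IRMS delta calibration curve
#'
#' Ordinary least squares of certified on measured delta values over the
#' run's reference materials: `certified = slope * measured + intercept`.
#' With exactly two standards this is the exact two-point line, so applying
#' the curve to either standard's own measurement reproduces its certified
#' value. Correction of sample deltas is `predict()`.
#'
#' @param measured numeric vector of measured delta values, one per
#'   standard.
#' @param certified numeric vector of certified delta values (same order),
#'   e.g. from [isotope_standards()].
#' @param names optional standard names, kept for the record.
#' @return object of class `delta_calibration`: list with `slope`,
#'   `intercept`, `standards` (data.frame), `residuals`.
#' @export
calibrate_delta <- function(measured, certified, names = NULL) {
  ok <- is.finite(measured) & is.finite(certified)
  measured <- measured[ok]
  certified <- certified[ok]
  if (length(measured) < 2) {
    stop("need >= 2 standards with finite values", call. = FALSE)
  }
  if (length(unique(measured)) < 2) {
    stop("measured values are not distinct; calibration fit is singular",
         call. = FALSE)
  }
  fit <- stats::lm(certified ~ measured)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         standards = data.frame(
           name = if (is.null(names)) paste0("std", seq_along(measured))
                  else names[ok],
           measured = measured, certified = certified,
           stringsAsFactors = FALSE),
         residuals = unname(stats::residuals(fit))),
    class = "delta_calibration"
  )
}

#' @export
print.delta_calibration <- function(x, ...) {
  cat(sprintf(
    "delta_calibration: corrected = %.5f * measured + %.5f (%d standards)\n",
    x$slope, x$intercept, nrow(x$standards)))
  invisible(x)
}

#' @param object a `delta_calibration`.
#' @param newdata numeric vector of measured delta values to correct.
#' @param ... unused.
#' @rdname calibrate_delta
#' @export
predict.delta_calibration <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

#' Excess atom percent over the unlabelled control
#'
#' Label incorporation is the atom percent of the enriched sample minus the
#' atom percent of the unlabelled control. Negative excess (label below
#' control, i.e. measurement noise) is preserved, not clipped, and flagged
#' through the `below_control` attribute so downstream budget steps can
#' apply their flooring policy explicitly.
#'
#' @param labelled atom percent of the labelled sample, in \[0, 100\].
#' @param control atom percent of the unlabelled control, in \[0, 100\].
#' @return excess atom percent (possibly negative), with logical attribute
#'   `below_control`.
#' @export
excess_atom_percent <- function(labelled, control) {
  for (v in list(labelled, control)) {
    if (any(v < 0) || any(v > 100)) {
      stop("atom percent must be in [0, 100]", call. = FALSE)
    }
  }
  out <- labelled - control
  attr(out, "below_control") <- out < 0
  out
}

#' Elemental-content standard curve and lookup
#'
#' Fits the linear thermal-conductivity-detector curve mapping detector
#' signal (peak area) to micrograms of element, from standards of known
#' mass and element percentage (`mass_ug * pct / 100` micrograms of
#' element), then converts sample signals with `predict()`.
#'
#' @param area numeric vector of detector signals for the standards.
#' @param mass_ug standard amounts weighed in, micrograms of compound.
#' @param pct element mass percentage of the standard compound (scalar or
#'   vector), e.g. `element_standards()$pct_C[1]` for sulfanilamide.
#' @return object of class `element_curve` (a wrapped `lm`).
#' @export
element_curve <- function(area, mass_ug, pct) {
  element_ug <- mass_ug * pct / 100
  if (length(area) < 2 || length(unique(area)) < 2) {
    stop("need >= 2 distinct signal points for the standard curve",
         call. = FALSE)
  }
  fit <- stats::lm(element_ug ~ area)
  structure(list(fit = fit,
                 points = data.frame(area = area, element_ug = element_ug)),
            class = "element_curve")
}

#' @param object an `element_curve`.
#' @param newdata numeric vector of sample detector signals.
#' @param ... unused.
#' @rdname element_curve
#' @export
predict.element_curve <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, data.frame(area = newdata)))
}

#' @rdname element_curve
#' @export
element_content <- function(object, area) {
  stopifnot(inherits(object, "element_curve"))
  predict(object, area)
}

#' Read isotope measurements from tidy TSV
#'
#' One row per measurement with columns `compartment`, `element` (C or N),
#' `time_point` (`1d`, `1w`, `2w`), `treatment` (`labelled` or `control`),
#' `value`, `value_kind` (`delta_permil`, `atom_percent` or `ratio`);
#' optional extra columns (e.g. `replicate`, `mass_ug`) are kept.
#' Range checks follow the value kind: atom percent in \[0, 100\], ratios
#' positive, deltas above -1000 permil.
#'
#' @param path tab-separated UTF-8 file with header row.
#' @return data.frame of validated measurements (zero rows, with a warning,
#'   for an empty file).
#' @export
read_isotope <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("compartment", "element", "time_point", "treatment", "value",
            "value_kind")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty isotope measurement file: ", path, call. = FALSE)
    return(df)
  }
  validate_isotope(df)
}

validate_isotope <- function(df) {
  bad <- which(!(df$element %in% c("C", "N")))
  if (length(bad) > 0) {
    stop(sprintf("unknown element '%s' at row %d", df$element[bad[1]],
                 bad[1]), call. = FALSE)
  }
  bad <- which(!(df$treatment %in% c("labelled", "control")))
  if (length(bad) > 0) {
    stop(sprintf("unknown treatment '%s' at row %d", df$treatment[bad[1]],
                 bad[1]), call. = FALSE)
  }
  bad <- which(!(df$value_kind %in% c("delta_permil", "atom_percent",
                                      "ratio")))
  if (length(bad) > 0) {
    stop(sprintf("unknown value_kind '%s' at row %d", df$value_kind[bad[1]],
                 bad[1]), call. = FALSE)
  }
  ap <- df$value_kind == "atom_percent"
  bad <- which(ap & (df$value < 0 | df$value > 100))
  if (length(bad) > 0) {
    stop(sprintf("atom_percent outside [0, 100] at row %d (value %s)",
                 bad[1], format(df$value[bad[1]])), call. = FALSE)
  }
  bad <- which(df$value_kind == "ratio" & df$value <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive ratio at row %d", bad[1]), call. = FALSE)
  }
  bad <- which(df$value_kind == "delta_permil" & df$value <= -1000)
  if (length(bad) > 0) {
    stop(sprintf("delta below -1000 permil at row %d", bad[1]),
         call. = FALSE)
  }
  df
}

#' Summarize per-compartment excess over controls
#'
#' Converts every measurement to atom percent (deltas and ratios through
#' the element's reference ratio), averages replicates within (compartment,
#' element, time_point, treatment), and subtracts the control mean from the
#' labelled mean per (compartment, element, time_point).
#'
#' @param measurements data.frame as returned by [read_isotope()] or
#'   [generate_tracer()].
#' @param refs reference ratios, see [reference_ratios()].
#' @return data.frame with columns `compartment`, `element`, `time_point`,
#'   `n_labelled`, `n_control`, `excess` (atom percent) and `below_control`.
#' @export
summarize_excess <- function(measurements, refs = reference_ratios()) {
  df <- validate_isotope(measurements)
  R_ref <- unname(unlist(refs)[match(df$element, c("C", "N"))])
  ap <- ifelse(df$value_kind == "atom_percent", df$value,
        ifelse(df$value_kind == "delta_permil",
               delta_to_atom_percent(df$value, R_ref),
               100 * df$value / (1 + df$value)))
  key <- interaction(df$compartment, df$element, df$time_point, drop = TRUE,
                     sep = "\r")
  split_ap <- split(data.frame(ap = ap, treatment = df$treatment), key)
  rows <- lapply(names(split_ap), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    d <- split_ap[[k]]
    lab <- d$ap[d$treatment == "labelled"]
    ctl <- d$ap[d$treatment == "control"]
    if (length(lab) == 0 || length(ctl) == 0) {
      stop("compartment '", parts[1], "' (", parts[2], ", ", parts[3],
           ") lacks a labelled or control measurement", call. = FALSE)
    }
    exc <- mean(lab) - mean(ctl)
    data.frame(compartment = parts[1], element = parts[2],
               time_point = parts[3], n_labelled = length(lab),
               n_control = length(ctl), excess = exc,
               below_control = exc < 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$element, out$time_point, out$compartment), , drop = FALSE]
}

#' PLFA/NLFA biomarker map
#'
#' Assigns each diagnostic fatty acid to its microbial pool. The default is
#' the standard biomarker set: eleven bacterial PLFAs (i14:0, i15:0, a15:0,
#' i16:0, 16:1w7t, 17:1w7, a17:1w7, i17:0, cy17:0, 18:1w7c, cy19:0), PLFA
#' 10Me16:0 for actinomycetes, PLFA 18:2w6,9 for saprotrophic fungi, and
#' NLFA 16:1w5 for arbuscular mycorrhizal fungi.
#'
#' @param overrides optional data.frame with columns `fatty_acid`, `pool`,
#'   `assay` replacing or extending default rows (matched on `fatty_acid` +
#'   `assay`).
#' @return data.frame with columns `fatty_acid`, `pool`, `assay`.
#' @export
biomarker_map <- function(overrides = NULL) {
  bacterial <- c("i14:0", "i15:0", "a15:0", "i16:0", "16:1w7t", "17:1w7",
                 "a17:1w7", "i17:0", "cy17:0", "18:1w7c", "cy19:0")
  map <- rbind(
    data.frame(fatty_acid = bacterial, pool = "bacteria", assay = "PLFA",
               stringsAsFactors = FALSE),
    data.frame(fatty_acid = "10Me16:0", pool = "actinomycetes",
               assay = "PLFA", stringsAsFactors = FALSE),
    data.frame(fatty_acid = "18:2w6,9", pool = "fungi", assay = "PLFA",
               stringsAsFactors = FALSE),
    data.frame(fatty_acid = "16:1w5", pool = "AMF", assay = "NLFA",
               stringsAsFactors = FALSE)
  )
  if (!is.null(overrides)) {
    need <- c("fatty_acid", "pool", "assay")
    if (!all(need %in% names(overrides))) {
      stop("overrides need columns fatty_acid, pool, assay", call. = FALSE)
    }
    key <- paste(map$fatty_acid, map$assay)
    okey <- paste(overrides$fatty_acid, overrides$assay)
    map <- rbind(map[!(key %in% okey), , drop = FALSE],
                 overrides[, need, drop = FALSE])
  }
  if (anyDuplicated(paste(map$fatty_acid, map$assay))) {
    stop("each (fatty acid, assay) must map to exactly one pool",
         call. = FALSE)
  }
  rownames(map) <- NULL
  map
}

#' Aggregate fatty-acid measurements into microbial pools
#'
#' Sums per-fatty-acid concentration and excess 13C into the biomarker
#' pools (bacteria, actinomycetes, fungi, AMF) and computes each mapped
#' fatty acid's percentage share of the total excess 13C across all mapped
#' biomarkers. Fatty acids absent from the map are ignored with a warning.
#'
#' @param fa data.frame with columns `fatty_acid`, `assay`, and one or both
#'   of `concentration` and `excess_13C`.
#' @param map biomarker map, see [biomarker_map()].
#' @return list with `pools` (per-pool sums) and `shares` (per-fatty-acid
#'   percentage of total excess, when `excess_13C` is present).
#' @export
aggregate_pools <- function(fa, map = biomarker_map()) {
  need <- c("fatty_acid", "assay")
  if (!all(need %in% names(fa))) {
    stop("fatty-acid table needs columns fatty_acid and assay",
         call. = FALSE)
  }
  key <- paste(fa$fatty_acid, fa$assay)
  mkey <- paste(map$fatty_acid, map$assay)
  hit <- key %in% mkey
  if (!any(hit)) {
    stop("no fatty acid in the table matches the biomarker map",
         call. = FALSE)
  }
  if (any(!hit)) {
    warning("ignoring unmapped fatty acid(s): ",
            paste(unique(fa$fatty_acid[!hit]), collapse = ", "),
            call. = FALSE)
  }
  fa <- fa[hit, , drop = FALSE]
  fa$pool <- map$pool[match(paste(fa$fatty_acid, fa$assay), mkey)]
  vars <- intersect(c("concentration", "excess_13C"), names(fa))
  if (length(vars) == 0) {
    stop("need a concentration or excess_13C column", call. = FALSE)
  }
  pools <- stats::aggregate(fa[vars], by = list(pool = fa$pool), FUN = sum)
  shares <- NULL
  if ("excess_13C" %in% vars) {
    total <- sum(fa$excess_13C)
    shares <- data.frame(fatty_acid = fa$fatty_acid, assay = fa$assay,
                         pool = fa$pool,
                         pct_of_total_excess =
                           if (total > 0) 100 * fa$excess_13C / total
                           else NA_real_,
                         stringsAsFactors = FALSE)
  }
  list(pools = pools, shares = shares)
}

#' Fungal-to-bacterial ratio
#'
#' F:B ratio on either biomass or excess-13C inputs. Vectorized over
#' per-sample values; `summarize = TRUE` additionally returns the mean and
#' standard deviation over samples (the ratio is computed per sample first,
#' which in general differs from the ratio of pooled sums).
#'
#' @param fungal numeric vector of fungal amounts (>= 0).
#' @param bacterial numeric vector of bacterial amounts (> 0).
#' @param summarize if `TRUE`, return a list with `ratios`, `mean`, `sd`.
#' @return per-sample ratios, or the summary list.
#' @export
fb_ratio <- function(fungal, bacterial, summarize = FALSE) {
  if (any(bacterial <= 0)) {
    stop("bacterial amount must be > 0", call. = FALSE)
  }
  if (any(fungal < 0)) stop("fungal amount must be >= 0", call. = FALSE)
  r <- fungal / bacterial
  if (!summarize) return(r)
  list(ratios = r, mean = mean(r), sd = stats::sd(r))
}

#' Partition labelled carbon among food-web pools
#'
#' Converts per-pool excess 13C into channel fractions (each pool's share
#' of the summed pool excess, summing to 1) and into root-scaled values
#' (pool excess divided by the total labelled carbon in the roots).
#' Pools with negative excess — label below control — are floored at 0
#' before partitioning and flagged; the raw excess is kept in the output.
#'
#' @param pool_excess named numeric vector of per-pool excess 13C (e.g.
#'   bacteria, fungi, AMF at the 1-day time point, or the consumer groups
#'   at 1 week and predators at 2 weeks).
#' @param root_excess total labelled carbon in the roots, same units (> 0).
#' @return object of class `tracer_budget`: data.frame with columns `pool`,
#'   `excess`, `floored`, `fraction`, `root_scaled`, plus attribute
#'   `root_excess`.
#' @export
#' @examples
#' channel_partition(c(bacteria = 1, fungi = 2, AMF = 1), root_excess = 8)
channel_partition <- function(pool_excess, root_excess) {
  if (is.null(names(pool_excess)) || any(!nzchar(names(pool_excess)))) {
    stop("pool_excess must be a named vector", call. = FALSE)
  }
  if (length(root_excess) != 1 || !is.finite(root_excess) ||
      root_excess <= 0) {
    stop("root_excess must be a single positive number", call. = FALSE)
  }
  floored <- pool_excess < 0
  pos <- pmax(pool_excess, 0)
  if (sum(pos) <= 0) {
    stop("all pool excesses are <= 0; no label to partition", call. = FALSE)
  }
  out <- data.frame(
    pool = names(pool_excess),
    excess = unname(pool_excess),
    floored = unname(floored),
    fraction = unname(pos / sum(pos)),
    root_scaled = unname(pos / root_excess),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("tracer_budget", "data.frame"),
            root_excess = root_excess)
}

#' @export
print.tracer_budget <- function(x, ...) {
  cat(sprintf("tracer_budget: %d pools, root excess = %g\n",
              nrow(x), attr(x, "root_excess")))
  print.data.frame(x, digits = 4)
  if (any(x$floored)) {
    cat("note: pool(s) below control floored at 0: ",
        paste(x$pool[x$floored], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
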