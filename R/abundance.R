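#' Stage labels and the default site-to-stage assignment
#'
#' Succession stage is a closed vocabulary: `recent`, `mid`, `long`. The
#' default map assigns the nine chronosequence site codes to stages (OR, REY,
#' TW recently abandoned; MO, NR, WV mid-term; MV, DK, BB long-term).
#' Synthetic site codes can be added through the `extra` argument or a YAML
#' config (`stage_map:` section).
#'
#' @param extra named character vector mapping additional site codes to
#'   stages, e.g. `c(S1 = "recent")`.
#' @return named character vector site code -> stage label.
#' @export
#' @examples
#' default_stage_map()[["OR"]]
default_stage_map <- function(extra = NULL) {
  map <- c(
    OR = "recent", REY = "recent", TW = "recent",
    MO = "mid", NR = "mid", WV = "mid",
    MV = "long", DK = "long", BB = "long"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop("`extra` must be a named vector of site codes", call. = FALSE)
    }
    bad <- setdiff(unique(extra), stage_levels())
    if (length(bad) > 0) {
      stop("unknown stage label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(extra)] <- extra
  }
  map
}

stage_levels <- function() c("recent", "mid", "long")

#' Construct an abundance table
#'
#' The substrate for all network statistics: a non-negative taxon x sample
#' matrix with per-taxon annotations (subgroup, main group, trophic function)
#' and per-sample annotations (site, subplot, succession stage). Abundances
#' may be in heterogeneous units across taxa (sequence reads, microscope
#' counts, percentage cover); downstream statistics only ever compare taxa
#' through ranks, never across taxa on the raw scale.
#'
#' @param values numeric matrix, taxa in rows, samples in columns, with
#'   dimnames giving taxon and sample ids.
#' @param taxon_meta data.frame with columns `taxon_id`, `subgroup`,
#'   `main_group`, `trophic_function` (extra columns kept).
#' @param sample_meta data.frame with columns `sample_id`, `site`, `subplot`,
#'   `stage`; `stage` must be one of `recent`, `mid`, `long`.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, taxon_meta, sample_meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  obj <- structure(
    list(values = values,
         taxon_meta = as.data.frame(taxon_meta),
         sample_meta = as.data.frame(sample_meta)),
    class = "abundance_table"
  )
  validate_abundance_table(obj)
}

#' @export
print.abundance_table <- function(x, ...) {
  st <- table(x$sample_meta$stage)
  cat(sprintf("abundance_table: %d taxa x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  stages: ",
      paste(sprintf("%s (%d)", names(st), as.integer(st)), collapse = ", "),
      "\n", sep = "")
  cat("  subgroups: ", length(unique(x$taxon_meta$subgroup)),
      "; main groups: ", length(unique(x$taxon_meta$main_group)),
      "\n", sep = "")
  invisible(x)
}

validate_abundance_table <- function(x) {
  v <- x$values
  if (!all(is.finite(v))) {
    stop("abundance values must be finite", call. = FALSE)
  }
  if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance for taxon '%s', sample '%s'",
                 rownames(v)[idx[1]], colnames(v)[idx[2]]), call. = FALSE)
  }
  need_t <- c("taxon_id", "subgroup", "main_group", "trophic_function")
  miss <- setdiff(need_t, names(x$taxon_meta))
  if (length(miss) > 0) {
    stop("taxon_meta missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  need_s <- c("sample_id", "site", "subplot", "stage")
  miss <- setdiff(need_s, names(x$sample_meta))
  if (length(miss) > 0) {
    stop("sample_meta missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$taxon_meta$taxon_id) ||
      !setequal(rownames(v), x$taxon_meta$taxon_id) ||
      nrow(x$taxon_meta) != nrow(v)) {
    stop("taxon_meta must list each row taxon exactly once", call. = FALSE)
  }
  if (anyDuplicated(x$sample_meta$sample_id) ||
      !setequal(colnames(v), x$sample_meta$sample_id) ||
      nrow(x$sample_meta) != ncol(v)) {
    stop("sample_meta must list each column sample exactly once",
         call. = FALSE)
  }
  bad <- setdiff(unique(x$sample_meta$stage), stage_levels())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # align metadata order with matrix order
  x$taxon_meta <- x$taxon_meta[match(rownames(v), x$taxon_meta$taxon_id), ,
                               drop = FALSE]
  x$sample_meta <- x$sample_meta[match(colnames(v), x$sample_meta$sample_id), ,
                                 drop = FALSE]
  rownames(x$taxon_meta) <- NULL
  rownames(x$sample_meta) <- NULL
  st <- table(x$sample_meta$stage)
  if (any(st < 2)) {
    stop("each stage needs >= 2 samples (correlation is undefined otherwise); ",
         "offending stage(s): ",
         paste(names(st)[st < 2], collapse = ", "), call. = FALSE)
  }
  x
}

#' Read an abundance table from tidy long-format TSV
#'
#' Expects one row per (taxon, sample) observation with columns `taxon_id`,
#' `sample_id`, `abundance`, the taxon annotations `subgroup`, `main_group`,
#' `trophic_function` and the sample annotations `site`, `subplot`, `stage`.
#' Pairs absent from the file get abundance 0. Duplicate (taxon, sample)
#' rows are an error.
#'
#' @param path path to a tab-separated UTF-8 file with a header row.
#' @param stage_map optional named vector site -> stage used to fill in a
#'   missing `stage` column; defaults to [default_stage_map()].
#' @return an [abundance_table()].
#' @seealso [write_abundance()]
#' @export
read_abundance <- function(path, stage_map = default_stage_map()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon_id", "sample_id", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!("stage" %in% names(df))) {
    if (!("site" %in% names(df))) {
      stop("missing required column(s): stage (or site, to derive it)",
           call. = FALSE)
    }
    df$stage <- unname(stage_map[df$site])
    if (anyNA(df$stage)) {
      stop("site code(s) not in stage map: ",
           paste(unique(df$site[is.na(df$stage)]), collapse = ", "),
           call. = FALSE)
    }
  }
  bad_stage <- !(df$stage %in% stage_levels())
  if (any(bad_stage)) {
    stop(sprintf("unknown stage label '%s' at row %d",
                 df$stage[which(bad_stage)[1]], which(bad_stage)[1]),
         call. = FALSE)
  }
  if (!is.numeric(df$abundance)) {
    stop("abundance column must be numeric", call. = FALSE)
  }
  neg <- which(df$abundance < 0 | !is.finite(df$abundance))
  if (length(neg) > 0) {
    stop(sprintf("invalid abundance at row %d (value %s)",
                 neg[1], format(df$abundance[neg[1]])), call. = FALSE)
  }
  dup <- duplicated(df[, c("taxon_id", "sample_id")])
  if (any(dup)) {
    stop(sprintf("duplicate (taxon, sample) observation at row %d",
                 which(dup)[1]), call. = FALSE)
  }
  for (col in c("subgroup", "main_group", "trophic_function")) {
    if (!(col %in% names(df))) df[[col]] <- "unassigned"
  }
  for (col in c("site", "subplot")) {
    if (!(col %in% names(df))) df[[col]] <- NA
  }
  taxa <- unique(df$taxon_id)
  samples <- unique(df$sample_id)
  values <- matrix(0, nrow = length(taxa), ncol = length(samples),
                   dimnames = list(taxa, samples))
  values[cbind(match(df$taxon_id, taxa), match(df$sample_id, samples))] <-
    df$abundance
  taxon_meta <- unique(df[, c("taxon_id", "subgroup", "main_group",
                              "trophic_function")])
  if (anyDuplicated(taxon_meta$taxon_id)) {
    stop("inconsistent taxon annotations for taxon '",
         taxon_meta$taxon_id[duplicated(taxon_meta$taxon_id)][1], "'",
         call. = FALSE)
  }
  sample_meta <- unique(df[, c("sample_id", "site", "subplot", "stage")])
  if (anyDuplicated(sample_meta$sample_id)) {
    stop("inconsistent sample annotations for sample '",
         sample_meta$sample_id[duplicated(sample_meta$sample_id)][1], "'",
         call. = FALSE)
  }
  abundance_table(values, taxon_meta, sample_meta)
}

#' Write an abundance table as tidy long-format TSV
#'
#' Inverse of [read_abundance()]: one row per (taxon, sample) pair including
#' explicit zeros, so `read_abundance(write_abundance(x))` is the identity.
#'
#' @param x an [abundance_table()].
#' @param path output path.
#' @param header optional character vector written as `#`-prefixed comment
#'   lines (provenance).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  v <- x$values
  df <- data.frame(
    taxon_id = rep(rownames(v), times = ncol(v)),
    sample_id = rep(colnames(v), each = nrow(v)),
    abundance = as.vector(v),
    stringsAsFactors = FALSE
  )
  df <- merge(df, x$taxon_meta, by = "taxon_id", sort = FALSE)
  df <- merge(df, x$sample_meta, by = "sample_id", sort = FALSE)
  df <- df[order(match(df$taxon_id, rownames(v)),
                 match(df$sample_id, colnames(v))),
           c("taxon_id", "sample_id", "abundance", "subgroup", "main_group",
             "trophic_function", "site", "subplot", "stage")]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce an abundance table to presence-absence
#'
#' Maps every positive abundance to 1 and keeps zeros, leaving annotations
#' untouched. The downstream pipeline is unchanged: Spearman correlation is
#' simply computed on the 0/1 vectors. Idempotent.
#'
#' @param x an [abundance_table()].
#' @return an [abundance_table()] with values in {0, 1}.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  x$values[] <- as.numeric(x$values > 0)
  x
}

#' Subset an abundance table to one stage and drop rare taxa
#'
#' Restricts the table to the samples of one succession stage and removes
#' every taxon that occurs (abundance > 0) in fewer than two of that stage's
#' samples — single-sample occurrences carry no co-occurrence information
#' and would otherwise inflate the correlation matrix. Taxa absent from all
#' samples are removed too.
#'
#' @param x an [abundance_table()].
#' @param stage one of `recent`, `mid`, `long`.
#' @param min_occurrences minimum number of stage samples a taxon must be
#'   present in to be retained (default 2).
#' @return an [abundance_table()] containing only the stage's samples and the
#'   retained taxa.
#' @export
filter_single_occurrence <- function(x, stage, min_occurrences = 2) {
  stopifnot(inherits(x, "abundance_table"))
  keep_s <- x$sample_meta$stage == stage
  if (!any(keep_s)) {
    stop("stage '", stage, "' not present in table", call. = FALSE)
  }
  sample_ids <- x$sample_meta$sample_id[keep_s]
  v <- x$values[, sample_ids, drop = FALSE]
  occ <- rowSums(v > 0)
  keep_t <- occ >= min_occurrences
  if (!any(keep_t)) {
    stop("no taxa occur in >= ", min_occurrences, " samples of stage '",
         stage, "'", call. = FALSE)
  }
  structure(
    list(values = v[keep_t, , drop = FALSE],
         taxon_meta = x$taxon_meta[keep_t, , drop = FALSE],
         sample_meta = x$sample_meta[keep_s, , drop = FALSE]),
    class = "abundance_table"
  )
}
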