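#' Generate a synthetic genome annotation
#'
#' Places `n_operons` non-overlapping transcription units along a linear
#' genome, each holding 1 to several same-strand features, and decorates them
#' with the marks the downstream classifier consumes: operon membership and
#' position, internal promoter / terminator marks between members,
#' opposite-strand partner features, sigma-factor promoter-motif flags on
#' planted regulon operon leaders (and on features downstream of internal
#' promoters within those operons), and "previously reported" regulon flags.
#' The leader of the first regulon operon is named `sigW` so that profile
#' clustering can tag the reference cluster; its neighbour (when present) is
#' named `rsiW`.
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` of class `"genome_annotation"` with columns
#'   `feature`, `start`, `end`, `strand`, `type`, `operon`, `operon_pos`,
#'   `regulon_operon`, `motif`, `prior_regulon`, `internal_promoter_before`,
#'   `terminator_after`, `antisense_of`. Coordinates are 1-based closed.
#' @examples
#' ann <- generate_annotation(simulation_config(n_operons = 4,
#'                                              genome_length = 20000))
#' head(ann)
#' @export
generate_annotation <- function(config) {
  validate_config(config)
  set.seed(config$seed + 1L)

  resample1 <- function(x) x[sample.int(length(x), 1L)]
  n_genes <- integer(config$n_operons)
  gene_lens <- vector("list", config$n_operons)
  gpo <- seq(config$genes_per_operon[1], config$genes_per_operon[2])
  for (i in seq_len(config$n_operons)) {
    n_genes[i] <- resample1(gpo)
    gene_lens[[i]] <- sample(400:1200, n_genes[i], replace = TRUE)
  }
  operon_gaps <- sample(200:800, config$n_operons, replace = TRUE)
  intra_gaps <- lapply(n_genes, function(k) sample(20:80, k, replace = TRUE))

  needed <- sum(unlist(gene_lens)) + sum(operon_gaps) + sum(unlist(intra_gaps))
  if (needed > config$genome_length)
    stop(sprintf(paste0("genome_length %d too short for the requested layout: ",
                        "%d bases needed (deficit %d)"),
                 config$genome_length, needed, needed - config$genome_length))

  n_reg <- if (config$regulon_fraction > 0)
    max(1L, round(config$regulon_fraction * config$n_operons)) else 0L
  regulon_operons <- sort(sample(seq_len(config$n_operons), n_reg))
  # the designated sigma-factor operon comes first so its leader anchors the
  # reference cluster
  strands <- sample(c("+", "-"), config$n_operons, replace = TRUE)

  rows <- vector("list", config$n_operons)
  pos <- 1L
  feat_counter <- 0L
  for (i in seq_len(config$n_operons)) {
    pos <- pos + operon_gaps[i]
    k <- n_genes[i]
    op_id <- sprintf("op%03d", i)
    is_reg <- i %in% regulon_operons
    # internal promoter / terminator marks only make sense between members
    ip_before <- rep(FALSE, k)
    term_after <- rep(FALSE, k)
    if (k > 1L && runif(1) < config$internal_promoter_fraction)
      ip_before[resample1(2:k)] <- TRUE
    if (k > 1L && runif(1) < config$terminator_fraction)
      term_after[resample1(seq_len(k - 1L))] <- TRUE
    starts <- ends <- integer(k)
    for (j in seq_len(k)) {
      starts[j] <- pos
      ends[j] <- pos + gene_lens[[i]][j] - 1L
      pos <- ends[j] + intra_gaps[[i]][j]
    }
    ids <- sprintf("g%04d", feat_counter + seq_len(k))
    feat_counter <- feat_counter + k
    motif <- rep(FALSE, k)
    if (is_reg) motif[1] <- TRUE
    if (is_reg) motif[ip_before] <- TRUE
    prior <- is_reg & (runif(k) < config$prior_regulon_fraction)
    rows[[i]] <- data.frame(feature = ids, start = starts, end = ends,
                            strand = strands[i], type = "gene",
                            operon = op_id, operon_pos = seq_len(k),
                            regulon_operon = is_reg, motif = motif,
                            prior_regulon = prior,
                            internal_promoter_before = ip_before,
                            terminator_after = term_after,
                            antisense_of = NA_character_,
                            stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)

  # name the sigma-factor operon leader(s)
  if (n_reg > 0L) {
    lead <- which(ann$operon == sprintf("op%03d", regulon_operons[1]))
    ann$feature[lead[1]] <- "sigW"
    if (length(lead) > 1L) ann$feature[lead[2]] <- "rsiW"
  }

  # opposite-strand partners overlapping the 5' region of their mate
  n_as <- round(config$antisense_fraction * nrow(ann))
  if (n_as > 0L) {
    mates <- sample(seq_len(nrow(ann)), n_as)
    as_rows <- ann[mates, ]
    five_prime <- ifelse(as_rows$strand == "+", as_rows$start, as_rows$end)
    as_start <- pmax(1L, as.integer(five_prime - 100L))
    as_end <- pmin(config$genome_length, as.integer(five_prime + 200L))
    as_df <- data.frame(feature = paste0("as_", as_rows$feature),
                        start = as_start, end = as_end,
                        strand = ifelse(as_rows$strand == "+", "-", "+"),
                        type = "antisense",
                        operon = paste0("as_", as_rows$feature),
                        operon_pos = 1L, regulon_operon = FALSE,
                        motif = FALSE, prior_regulon = FALSE,
                        internal_promoter_before = FALSE,
                        terminator_after = FALSE,
                        antisense_of = as_rows$feature,
                        stringsAsFactors = FALSE)
    ann <- rbind(ann, as_df)
  }

  ann <- ann[order(ann$start, ann$end), ]
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

annotation_flag_cols <- c("regulon_operon", "motif", "prior_regulon",
                          "internal_promoter_before", "terminator_after")

validate_annotation <- function(ann) {
  req <- c("feature", "start", "end", "strand", "operon", "operon_pos")
  missing <- setdiff(req, names(ann))
  if (length(missing))
    stop("annotation lacks required columns: ", paste(missing, collapse = ", "))
  if (any(ann$end < ann$start))
    stop("annotation has features with end < start: ",
         paste(ann$feature[ann$end < ann$start], collapse = ", "))
  if (!all(ann$strand %in% c("+", "-")))
    stop("unknown strand symbol in annotation (must be '+' or '-')")
  if (anyDuplicated(ann$feature))
    stop("duplicated feature ids in annotation")
  invisible(ann)
}

#' Convert an annotation to GRanges
#'
#' @param ann A `genome_annotation` data.frame.
#' @param seqname Chromosome name used for the single replicon.
#' @return A [GenomicRanges::GRanges] with the annotation columns as metadata.
#' @export
annotation_granges <- function(ann, seqname = "chr") {
  validate_annotation(ann)
  gr <- GenomicRanges::GRanges(seqnames = seqname,
                               ranges = IRanges::IRanges(ann$start, ann$end),
                               strand = ann$strand)
  meta <- ann[, setdiff(names(ann), c("start", "end", "strand")), drop = FALSE]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  gr
}

#' Write an annotation as GFF3
#'
#' Features are written as 1-based closed intervals with the operon id,
#' promoter/terminator marks, motif and prior-regulon flags carried as GFF3
#' attributes, so that a written annotation reads back identically.
#'
#' @param ann A `genome_annotation` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_annotation()]
#' @export
write_annotation <- function(ann, path) {
  gr <- annotation_granges(ann)
  names(gr) <- NULL
  mc <- S4Vectors::mcols(gr)
  mc$ID <- mc$feature
  if (!"type" %in% names(mc)) mc$type <- "gene"
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' Light structural validation (field count, coordinates, strand vocabulary)
#' is performed first so that malformed lines are reported with their line
#' number; parsing itself is done by [rtracklayer::import()]. Absent flag
#' attributes default to `FALSE`, an absent operon id defaults to the feature
#' id (a single-gene transcription unit).
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` of class `"genome_annotation"`, coordinate-sorted,
#'   with 1-based closed intervals.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop(sprintf("malformed GFF3 line %d: bad coordinates '%s'..'%s'",
                   i, f[4], f[5]))
    if (!f[7] %in% c("+", "-"))
      stop(sprintf("unknown strand symbol '%s' on GFF3 line %d", f[7], i))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  feature <- if ("feature" %in% names(mc)) mc$feature else mc$ID
  ann <- data.frame(feature = as.character(feature),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    type = if ("type" %in% names(mc)) as.character(mc$type) else "gene",
                    stringsAsFactors = FALSE)
  ann$operon <- if ("operon" %in% names(mc)) as.character(mc$operon) else ann$feature
  ann$operon_pos <- if ("operon_pos" %in% names(mc))
    as.integer(as.character(mc$operon_pos)) else 1L
  for (fl in annotation_flag_cols)
    ann[[fl]] <- if (fl %in% names(mc)) as.logical(as.character(mc[[fl]])) else FALSE
  ann$antisense_of <- if ("antisense_of" %in% names(mc))
    as.character(mc$antisense_of) else NA_character_
  ann <- ann[order(ann$start, ann$end), ]
  rownames(ann) <- NULL
  validate_annotation(ann)
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}
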