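#' Intersect SVs with gene bodies, CDS and promoters
#'
#' A gene is "affected" by an SV if the SV's reference footprint (its
#' interior interval; for insertions, the anchor point) intersects the
#' gene body, a CDS interval, or the promoter — the 2 kb upstream of the
#' transcription start site (downstream in reference coordinates for
#' minus-strand genes). Promoters that would extend past the chromosome
#' start are truncated with a warning.
#'
#' @param svs An `sv_set` from [call_svs()].
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), or a `GRanges` with a `gene_id`
#'   column. The TSS is the strand-appropriate end of the body.
#' @param cds Optional `data.frame(gene_id, chrom, start, end)` of CDS
#'   intervals.
#' @param promoter_len Promoter length in bp upstream of the TSS
#'   (default 2000).
#' @return List with `overlaps` (`data.frame`: gene_id, sv_id, region in
#'   `{CDS, gene_body, promoter}`; one row per gene/SV/region),
#'   `genes_affected` (character vector) and `fraction_affected`.
#' @export
sv_gene_overlap <- function(svs, genes, cds = NULL, promoter_len = 2000) {
  stopifnot(inherits(svs, "sv_set"))
  genes <- as_gene_df(genes)
  sv_gr <- sv_footprint(svs)
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))

  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  p_start <- ifelse(genes$strand == "+", tss - promoter_len, tss + 1L)
  p_end <- ifelse(genes$strand == "+", tss - 1L, tss + promoter_len)
  if (any(p_start < 1)) {
    warning("promoter truncated at chromosome start for ",
            sum(p_start < 1), " gene(s)")
    p_start <- pmax(p_start, 1L)
    p_end <- pmax(p_end, 1L)
  }
  prom_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(p_start, p_end))

  collect <- function(region_gr, gene_ids, label) {
    h <- GenomicRanges::findOverlaps(sv_gr, region_gr)
    if (length(h) == 0) return(NULL)
    data.frame(gene_id = gene_ids[S4Vectors::subjectHits(h)],
               sv_id = names(sv_gr)[S4Vectors::queryHits(h)],
               region = label, stringsAsFactors = FALSE)
  }
  res <- rbind(collect(body_gr, genes$gene_id, "gene_body"),
               collect(prom_gr, genes$gene_id, "promoter"))
  if (!is.null(cds) && nrow(cds)) {
    cds_gr <- GenomicRanges::GRanges(
      cds$chrom, IRanges::IRanges(cds$start, cds$end))
    res <- rbind(res, collect(cds_gr, cds$gene_id, "CDS"))
  }
  if (is.null(res))
    res <- data.frame(gene_id = character(0), sv_id = character(0),
                      region = character(0))
  res <- unique(res[order(res$gene_id, res$sv_id, res$region), ])
  rownames(res) <- NULL
  affected <- sort(unique(res$gene_id))
  list(overlaps = res, genes_affected = affected,
       fraction_affected = length(affected) / nrow(genes))
}

as_gene_df <- function(genes) {
  if (methods::is(genes, "GRanges")) {
    genes <- data.frame(
      gene_id = S4Vectors::mcols(genes)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes),
      end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand")
                %in% names(genes)))
  genes
}

# Reference footprint of each SV as a GRanges: interior interval
# [pos + 1, end] for variants with a reference footprint; the anchor
# point [pos, pos] for pure insertions (zero-length reference interior).
sv_footprint <- function(svs) {
  has_fp <- svs$end > svs$pos
  gr <- GenomicRanges::GRanges(
    svs$chrom,
    IRanges::IRanges(ifelse(has_fp, svs$pos + 1L, svs$pos),
                     svs$end))
  names(gr) <- paste0(svs$chrom, ":", svs$pos)
  gr
}

#' Flag SVs whose alleles derive from transposable elements
#'
#' An SV is TE-associated when some allele is covered by TE annotation
#' over at least `min_fraction` of its length. Two annotation spaces are
#' supported in the same table: rows whose `chrom` names a reference
#' chromosome are intersected with the SV's reference footprint, and
#' rows whose `chrom` names an allele (`"<chrom>:<pos>:<k>"` for the
#' k-th alternate allele) are intersected with that allele's own
#' coordinates — the natural encoding for TE content carried by
#' insertion alleles.
#'
#' @param svs An `sv_set`.
#' @param te_intervals `data.frame(chrom, start, end, class)`.
#' @param min_fraction Minimum covered fraction of the allele length
#'   (default 0.5).
#' @return `data.frame`: sv_id, te_flag, te_class (class with the
#'   largest coverage, `NA` if unflagged), coverage (best fraction).
#' @export
sv_te_overlap <- function(svs, te_intervals, min_fraction = 0.5) {
  stopifnot(inherits(svs, "sv_set"))
  n <- nrow(svs)
  out <- data.frame(sv_id = paste0(svs$chrom, ":", svs$pos),
                    te_flag = rep(FALSE, n), te_class = NA_character_,
                    coverage = rep(0, n), stringsAsFactors = FALSE)
  if (is.null(te_intervals) || nrow(te_intervals) == 0) return(out)
  te <- te_intervals
  cov_on <- function(space, lo, hi) {
    # total covered bp and best class of [lo, hi] on coordinate space
    hit <- te[te$chrom == space & te$end >= lo & te$start <= hi, ,
              drop = FALSE]
    if (nrow(hit) == 0) return(list(bp = 0, class = NA_character_))
    w <- pmin(hit$end, hi) - pmax(hit$start, lo) + 1
    r <- IRanges::reduce(IRanges::IRanges(pmax(hit$start, lo),
                                          pmin(hit$end, hi)))
    list(bp = sum(IRanges::width(r)), class = hit$class[which.max(w)])
  }
  for (i in seq_len(n)) {
    alts <- svs$alt_alleles[[i]]
    best <- 0; best_class <- NA_character_
    # reference-footprint alleles (deletion/divergent footprints)
    if (svs$end[i] > svs$pos[i]) {
      fp_len <- svs$end[i] - svs$pos[i]
      cv <- cov_on(svs$chrom[i], svs$pos[i] + 1L, svs$end[i])
      frac <- cv$bp / fp_len
      if (frac > best) { best <- frac; best_class <- cv$class }
    }
    # allele-space annotations
    for (k in seq_along(alts)) {
      len <- nchar(alts[k])
      if (len == 0) next
      cv <- cov_on(sprintf("%s:%d:%d", svs$chrom[i], svs$pos[i], k), 1L, len)
      frac <- cv$bp / len
      if (frac > best) { best <- frac; best_class <- cv$class }
    }
    out$coverage[i] <- best
    if (best >= min_fraction && best > 0) {
      out$te_flag[i] <- TRUE
      out$te_class[i] <- best_class
    }
  }
  out
}

#' SV density in sliding windows with hotspot flagging
#'
#' Counts SVs by anchor position in sliding windows (default 50 kb
#' windows, 20 kb step) and flags windows whose count reaches the
#' genome-wide `1 - top_fraction` quantile (default: top 5% of window
#' densities). Windows with zero SVs are never hotspots.
#'
#' @param svs An `sv_set`.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param window Window size in bp (default 50000).
#' @param step Step size in bp (default 20000); must satisfy
#'   `window >= step > 0`.
#' @param top_fraction Fraction of windows flagged (default 0.05).
#' @return `data.frame`: chrom, start, end, sv_count, is_hotspot; the
#'   hotspot count threshold is attached as attribute `"threshold"`.
#' @export
sv_density_hotspots <- function(svs, chrom_lengths, window = 50000,
                                step = 20000, top_fraction = 0.05) {
  stopifnot(inherits(svs, "sv_set"), window >= step, step > 0,
            top_fraction > 0, top_fraction <= 1,
            !is.null(names(chrom_lengths)))
  recs <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1L, max(1L, len), by = step)
    # drop starts beyond the chromosome; keep at least one window
    starts <- starts[starts <= len]
    ends <- pmin(starts + window - 1L, len)
    pos <- svs$pos[svs$chrom == ch]
    counts <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos <= ends[i]), 0L)
    data.frame(chrom = ch, start = starts, end = ends, sv_count = counts,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, recs)
  thr <- as.numeric(stats::quantile(d$sv_count, 1 - top_fraction))
  d$is_hotspot <- d$sv_count >= thr & d$sv_count > 0
  attr(d, "threshold") <- thr
  d
}

#' Read gene models from GFF3
#'
#' Extracts `gene` features (with `ID` or `gene_id` as the identifier)
#' and `CDS` features from a GFF3 file via `rtracklayer`.
#'
#' @param path GFF3 file.
#' @return List with `genes` and `cds` data frames as accepted by
#'   [sv_gene_overlap()].
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path)
  m <- S4Vectors::mcols(gff)
  id <- if ("gene_id" %in% names(m)) m$gene_id else as.character(m$ID)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gff)),
                   start = GenomicRanges::start(gff),
                   end = GenomicRanges::end(gff),
                   strand = as.character(GenomicRanges::strand(gff)),
                   type = as.character(m$type), gene_id = id,
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", c("gene_id", "chrom", "start", "end",
                                   "strand")]
  cds <- df[df$type == "CDS", c("gene_id", "chrom", "start", "end")]
  if (nrow(cds) && anyNA(cds$gene_id) && "Parent" %in% names(m)) {
    parent <- vapply(m$Parent, function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, "")
    cds$gene_id <- parent[df$type == "CDS"]
  }
  rownames(genes) <- rownames(cds) <- NULL
  list(genes = genes, cds = cds)
}

#' Read TE annotations from BED (class in the name field)
#' @param path BED file (>= 4 columns; 4th column is the TE class).
#' @return `data.frame(chrom, start, end, class)` with 1-based closed
#'   coordinates as used by [sv_te_overlap()].
#' @export
read_te_bed <- function(path) {
  b <- rtracklayer::import(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
             start = GenomicRanges::start(b), end = GenomicRanges::end(b),
             class = if (!is.null(b$name)) b$name else NA_character_,
             stringsAsFactors = FALSE)
}
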