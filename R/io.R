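#' Write / read a sequence graph in GFA 1.0
#'
#' Segments as `S` lines, links as `L` lines with `0M` overlap, one `P`
#' line per walk per chromosome named `<walk>#<chrom>`. The reference
#' walk is recorded in the header line as a `RW:Z:` tag.
#'
#' @param graph A `sequence_graph`.
#' @param path Output file.
#' @return `write_gfa` returns `path` invisibly; `read_gfa` returns a
#'   `sequence_graph`.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "sequence_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tRW:Z:%s", graph$reference_walk), con)
  writeLines(sprintf("S\t%s\t%s", names(graph$segments), graph$segments), con)
  if (nrow(graph$links))
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M",
                       graph$links$from, graph$links$from_orient,
                       graph$links$to, graph$links$to_orient), con)
  for (s in names(graph$walks)) for (ch in names(graph$walks[[s]])) {
    segs <- paste0(graph$walks[[s]][[ch]], "+", collapse = ",")
    writeLines(sprintf("P\t%s#%s\t%s\t*", s, ch, segs), con)
  }
  invisible(path)
}

#' @rdname write_gfa
#' @param reference_walk Name of the reference walk; default taken from
#'   the `RW:Z:` header tag.
#' @export
read_gfa <- function(path, reference_walk = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tag <- substr(lines, 1, 1)
  fields <- strsplit(lines, "\t", fixed = TRUE)

  hdr <- fields[tag == "H"]
  if (is.null(reference_walk) && length(hdr)) {
    rw <- grep("^RW:Z:", unlist(hdr), value = TRUE)
    if (length(rw)) reference_walk <- sub("^RW:Z:", "", rw[1])
  }
  if (is.null(reference_walk))
    stop_pansv("reference walk not named in GFA header; pass reference_walk=")

  sl <- fields[tag == "S"]
  segments <- stats::setNames(
    toupper(vapply(sl, `[[`, "", 3)), vapply(sl, `[[`, "", 2))

  ll <- fields[tag == "L"]
  links <- data.frame(
    from = vapply(ll, `[[`, "", 2), from_orient = vapply(ll, `[[`, "", 3),
    to = vapply(ll, `[[`, "", 4), to_orient = vapply(ll, `[[`, "", 5),
    stringsAsFactors = FALSE)

  pl <- fields[tag == "P"]
  walks <- list()
  for (p in pl) {
    name <- p[[2]]
    hash <- regexpr("#", name, fixed = TRUE)
    if (hash < 0)
      stop_pansv("P line '%s' is not named <walk>#<chrom>", name)
    s <- substr(name, 1, hash - 1L)
    ch <- substr(name, hash + 1L, nchar(name))
    segs <- sub("[+-]$", "", strsplit(p[[3]], ",", fixed = TRUE)[[1]])
    if (is.null(walks[[s]])) walks[[s]] <- list()
    walks[[s]][[ch]] <- segs
  }
  if (!reference_walk %in% names(walks))
    stop_pansv("reference walk '%s' has no P lines", reference_walk)
  ref_segs <- unique(unlist(walks[[reference_walk]]))
  origin <- stats::setNames(
    ifelse(names(segments) %in% ref_segs, "reference", "non-reference"),
    names(segments))
  g <- structure(list(segments = segments, links = links, walks = walks,
                      reference_walk = reference_walk,
                      segment_origin = origin),
                 class = "sequence_graph")
  validate_graph(g)
  g
}

SVTYPE_CODE <- c(biallelic_insertion = "INS", biallelic_deletion = "DEL",
                 biallelic_divergent = "DIV", multiallelic = "MULTI")

#' Write called SVs as VCF 4.2
#'
#' Uses the anchor-base convention: `POS` is the reference base
#' immediately before the bubble interior and both `REF` and `ALT`
#' alleles carry that base as a prefix, so empty interior alleles
#' (insertions/deletions) are represented losslessly. `INFO` carries
#' `SVTYPE` (`INS`/`DEL`/`DIV`/`MULTI`), `SVLEN` (maximum interior
#' allele length) and `END`; genotypes are homozygous (`0/0`, `1/1`,
#' ...) or missing (`./.`).
#'
#' @param svs An `sv_set`.
#' @param path Output file.
#' @param samples Sample column order; default the union of carriers.
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, samples = NULL, contig_lengths = NULL) {
  stopifnot(inherits(svs, "sv_set"))
  samples <- samples %||%
    sort(unique(unlist(c(svs$carriers, svs$ref_carriers))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pansv",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class: INS, DEL, DIV or MULTI">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Maximum allele length (bp), anchor base excluded">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End of the reference footprint">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype (homozygous convention)">'),
    con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (i in seq_len(nrow(svs))) {
    anchor <- svs$anchor_base[i]
    ref <- paste0(anchor, svs$ref_allele[i])
    alts <- paste0(anchor, svs$alt_alleles[[i]])
    gt <- rep("./.", length(samples))
    gt[samples %in% svs$ref_carriers[[i]]] <- "0/0"
    for (j in seq_along(alts)) {
      gt[samples %in% svs$carriers[[i]][[j]]] <- sprintf("%d/%d", j, j)
    }
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d",
                    SVTYPE_CODE[[svs$sv_type[i]]], svs$sv_length[i],
                    svs$end[i])
    writeLines(paste(c(svs$chrom[i], svs$pos[i],
                       sprintf("%s:%d", svs$chrom[i], svs$pos[i]),
                       ref, paste(alts, collapse = ","), ".", "PASS", info,
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an SV VCF written by [write_sv_vcf()]
#'
#' Parses through `vcfR` and strips the anchor base back off, returning
#' the same `sv_set` representation that [call_svs()] produces (anchor
#' segment ids are not stored in VCF and come back as `NA`).
#'
#' @param path VCF file.
#' @return An `sv_set`; the samples-by-SV genotype matrix is attached as
#'   attribute `"genotypes"`.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- if (ncol(v@gt) > 1) v@gt[, -1, drop = FALSE] else
    matrix(character(0), nrow(fix), 0)
  if (nrow(fix) && is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(gt) %||% character(0)
  recs <- list()
  gmat <- matrix(NA_real_, length(samples), nrow(fix),
                 dimnames = list(samples, fix$ID))
  for (i in seq_len(nrow(fix))) {
    ref <- substring(fix$REF[i], 2)
    alts <- substring(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]], 2)
    info <- strsplit(fix$INFO[i], ";", fixed = TRUE)[[1]]
    get_info <- function(key) {
      hit <- grep(paste0("^", key, "="), info, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA
    }
    svtype <- names(SVTYPE_CODE)[SVTYPE_CODE == get_info("SVTYPE")]
    codes <- sub(":.*", "", gt[i, ])
    a1 <- suppressWarnings(as.integer(sub("[/|].*", "", codes)))
    carriers <- lapply(seq_along(alts), function(j)
      sort(samples[!is.na(a1) & a1 == j]))
    ref_carriers <- sort(samples[!is.na(a1) & a1 == 0])
    multi <- length(alts) >= 2
    gmat[, i] <- ifelse(is.na(a1), NA_real_,
                        ifelse(a1 == 0, 0, if (multi) a1 else 2))
    recs[[i]] <- list(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      end = as.integer(get_info("END")),
      anchor_base = substr(fix$REF[i], 1, 1),
      ref_allele = ref, sv_type = svtype,
      sv_length = as.integer(get_info("SVLEN")),
      source = NA_character_, sink = NA_character_,
      alt_alleles = alts, carriers = carriers,
      ref_carriers = ref_carriers)
  }
  out <- sv_set(recs)
  attr(out, "genotypes") <- gmat
  out
}

#' Write sequences as FASTA
#' @param sequences Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read a haplotype variant table as TSV
#' @param variants `data.frame` as accepted by [build_graph()].
#' @param path File path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  d <- utils::read.delim(path, colClasses = c(ref_allele = "character",
                                              alt_allele = "character"))
  d$ref_allele[is.na(d$ref_allele)] <- ""
  d$alt_allele[is.na(d$alt_allele)] <- ""
  d
}

#' Write / read a two-column phenotype TSV (sample, value)
#' @param phenotype Named numeric vector.
#' @param path File path.
#' @return Named numeric vector (read) or `path` invisibly (write).
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(
    data.frame(sample = names(phenotype), value = unname(phenotype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  d <- utils::read.delim(path)
  stats::setNames(d$value, d$sample)
}

#' Write / read a genotype panel as a TSV matrix
#'
#' Layout: variant metadata columns (`id`, `chrom`, `pos`, `class`)
#' followed by one column per sample; missing genotypes as `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param path File path.
#' @return A `genotype_panel` (read) or `path` invisibly (write).
#' @export
write_panel_tsv <- function(panel, path) {
  d <- cbind(panel$variants[c("id", "chrom", "pos", "class")],
             as.data.frame(t(panel$genotypes)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c(chrom = "character"))
  meta <- c("id", "chrom", "pos", "class")
  samples <- setdiff(names(d), meta)
  g <- t(as.matrix(d[samples]))
  colnames(g) <- d$id
  genotype_panel(g, d[meta], samples)
}
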