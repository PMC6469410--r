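#' Read a GFF3 annotation into a gene model
#'
#' Features of type `gene`, `mRNA` and `exon` linked by `ID`/`Parent`
#' attributes are assembled into a [gene_model()].  GFF3 coordinates
#' (1-based, closed) are converted to the internal 0-based half-open
#' convention at this boundary.  Features whose source column is
#' `"beesplice"` are flagged `provenance = "novel"`; everything else is
#' `"annotated"`.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_model()].
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_model())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 9L
  if (any(bad)) stop("malformed GFF3 line: ", lines[bad][1L])
  f <- do.call(rbind, f)
  type <- f[, 3L]
  keep <- type %in% c("gene", "mRNA", "exon")
  f <- f[keep, , drop = FALSE]; type <- type[keep]
  if (nrow(f) == 0L) return(gene_model())
  start1 <- as.integer(f[, 4L]); end1 <- as.integer(f[, 5L])
  if (any(is.na(start1)) || any(is.na(end1))) stop("non-numeric GFF3 coordinate")
  if (any(start1 > end1)) {
    stop("GFF3 feature with start > end at line: ",
         paste(f[which(start1 > end1)[1L], 1:5], collapse = " "))
  }
  attr_field <- f[, 9L]
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- grepl(paste0("(^|;)", key, "="), attr_field)
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(attr_field,
                               regexpr(paste0("(^|;)", key, "=[^;]*"),
                                       attr_field)))
    out
  }
  ids <- get_attr("ID"); parents <- get_attr("Parent")
  prov <- ifelse(f[, 2L] == "beesplice", "novel", "annotated")
  chrom <- f[, 1L]; strand <- f[, 7L]
  start0 <- start1 - 1L; end0 <- end1

  is_g <- type == "gene"; is_t <- type == "mRNA"; is_e <- type == "exon"
  genes <- data.frame(gene_id = ids[is_g], chrom = chrom[is_g],
                      start = start0[is_g], end = end0[is_g],
                      strand = strand[is_g], provenance = prov[is_g],
                      stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute")
  transcripts <- data.frame(transcript_id = ids[is_t], gene_id = parents[is_t],
                            provenance = prov[is_t], stringsAsFactors = FALSE)
  if (anyNA(transcripts$transcript_id) || anyNA(transcripts$gene_id)) {
    stop("mRNA feature missing ID or Parent attribute")
  }
  tx2gene <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
  orphan_tx <- !transcripts$gene_id %in% genes$gene_id
  if (any(orphan_tx)) {
    stop("orphan Parent for mRNA ", transcripts$transcript_id[orphan_tx][1L],
         ": gene ", transcripts$gene_id[orphan_tx][1L], " not found")
  }
  epar <- parents[is_e]
  if (anyNA(epar)) stop("exon feature without Parent attribute")
  orphan_ex <- !epar %in% transcripts$transcript_id
  if (any(orphan_ex)) {
    stop("orphan Parent for exon: transcript ", epar[orphan_ex][1L],
         " not found")
  }
  exons <- data.frame(transcript_id = epar,
                      gene_id = unname(tx2gene[epar]),
                      chrom = chrom[is_e], start = start0[is_e],
                      end = end0[is_e], strand = strand[is_e],
                      provenance = prov[is_e], stringsAsFactors = FALSE)
  gene_model(genes, transcripts, exons)
}

#' Write a gene model as GFF3
#'
#' Output is deterministic: genes ordered by (chrom, start, ID), transcripts
#' by ID within gene, exons by start within transcript.  Novel features are
#' written with source `"beesplice"` so they can be distinguished from the
#' input annotation (source `"."`).
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(model, path) {
  src <- function(prov) ifelse(prov == "novel", "beesplice", ".")
  lines <- "##gff-version 3"
  g <- model$genes
  g <- g[order(g$chrom, g$start, g$gene_id), , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(g$chrom[i], src(g$provenance[i]), "gene",
                            g$start[i] + 1L, g$end[i], ".", g$strand[i], ".",
                            paste0("ID=", g$gene_id[i]), sep = "\t"))
    tx <- model$transcripts[model$transcripts$gene_id == g$gene_id[i], ,
                            drop = FALSE]
    tx <- tx[order(tx$transcript_id), , drop = FALSE]
    for (j in seq_len(nrow(tx))) {
      e <- model$exons[model$exons$transcript_id == tx$transcript_id[j], ,
                       drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      lines <- c(lines, paste(e$chrom[1L], src(tx$provenance[j]), "mRNA",
                              min(e$start) + 1L, max(e$end), ".",
                              e$strand[1L], ".",
                              paste0("ID=", tx$transcript_id[j], ";Parent=",
                                     tx$gene_id[j]), sep = "\t"))
      lines <- c(lines, paste(e$chrom, src(e$provenance), "exon",
                              e$start + 1L, e$end, ".", e$strand, ".",
                              paste0("Parent=", e$transcript_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read splice junctions from a 6-column TSV
#'
#' Columns: chrom, intron start (0-based, first intronic base), intron end
#' (one past the last intronic base), strand, confidence score in \[0,1\],
#' supporting read count.  Duplicate `(chrom, start, end, strand)` rows are
#' merged by summing support and taking the maximum score, matching how
#' junction calls from independent runs are clustered.
#'
#' @param path path to the junction TSV (header line starting with `#`).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `score`, `support`, sorted by (chrom, start, end).
#' @export
read_junctions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_junctions())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(f) < 6L) stop("junction TSV needs 6 columns")
  j <- data.frame(chrom = f[, 1L], start = as.integer(f[, 2L]),
                  end = as.integer(f[, 3L]), strand = f[, 4L],
                  score = as.numeric(f[, 5L]), support = as.integer(f[, 6L]),
                  stringsAsFactors = FALSE)
  validate_junctions(j)
  merge_junctions(j)
}

empty_junctions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), support = integer(),
             stringsAsFactors = FALSE)
}

validate_junctions <- function(j) {
  if (nrow(j) == 0L) return(invisible(j))
  if (any(is.na(j$score)) || any(j$score < 0) || any(j$score > 1)) {
    stop("junction score outside [0,1]")
  }
  if (any(is.na(j$support)) || any(j$support < 0L)) {
    stop("negative junction support")
  }
  if (any(j$end - j$start < 4L)) {
    stop("junction intron shorter than 4 bp (no room for GT..AG)")
  }
  if (!all(j$strand %in% c("+", "-"))) stop("junction strand must be + or -")
  invisible(j)
}

merge_junctions <- function(j) {
  if (nrow(j) == 0L) return(j)
  key <- paste(j$chrom, j$start, j$end, j$strand)
  support <- tapply(j$support, key, sum)
  score <- tapply(j$score, key, max)
  first <- !duplicated(key)
  out <- j[first, , drop = FALSE]
  k <- paste(out$chrom, out$start, out$end, out$strand)
  out$support <- as.integer(support[k])
  out$score <- as.numeric(score[k])
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_junctions
#' @param junctions junction data.frame as returned by [read_junctions()].
#' @export
write_junctions <- function(junctions, path) {
  lines <- "#chrom\tstart\tend\tstrand\tscore\tsupport"
  if (nrow(junctions) > 0L) {
    j <- junctions[order(junctions$chrom, junctions$start, junctions$end), ,
                   drop = FALSE]
    lines <- c(lines, paste(j$chrom, j$start, j$end, j$strand,
                            format_num(j$score), j$support, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# fixed-notation number formatting for deterministic files
format_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  trimws(out)
}

#' Read per-base coverage from a bedGraph file
#'
#' Intervals are expanded to per-base depth; bases not listed get depth 0.
#' Overlapping intervals with conflicting values are an error.
#'
#' @param path path to a bedGraph file.
#' @param chrom_lengths optional named integer vector of chromosome lengths;
#'   when omitted each chromosome's length is the largest interval end seen.
#' @return A `coverage_track`: a named list of per-base numeric depth vectors.
#' @export
read_coverage <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(trimws(lines))]
  if (length(lines) == 0L) return(coverage_track(list()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  chrom <- f[, 1L]; start <- as.integer(f[, 2L]); end <- as.integer(f[, 3L])
  value <- as.numeric(f[, 4L])
  if (any(value < 0)) stop("negative coverage value")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(end, chrom, max)
  }
  track <- lapply(stats::setNames(nm = names(chrom_lengths)), function(cn) {
    numeric(chrom_lengths[[cn]])
  })
  seen <- lapply(track, function(v) logical(length(v)))
  for (i in order(chrom, start)) {
    cn <- chrom[i]
    if (!cn %in% names(track)) stop("bedGraph chromosome not in lengths: ", cn)
    idx <- (start[i] + 1L):end[i]
    clash <- seen[[cn]][idx] & track[[cn]][idx] != value[i]
    if (any(clash)) {
      stop("overlapping bedGraph intervals with conflicting values on ", cn,
           " near base ", start[i] + which(clash)[1L] - 1L)
    }
    track[[cn]][idx] <- value[i]
    seen[[cn]][idx] <- TRUE
  }
  coverage_track(track)
}

#' @param depths named list of per-base non-negative depth vectors.
#' @rdname read_coverage
#' @export
coverage_track <- function(depths) {
  stopifnot(is.list(depths))
  if (any(vapply(depths, function(v) any(v < 0), logical(1)))) {
    stop("coverage depth must be >= 0")
  }
  structure(depths, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x), "chromosomes,",
      sum(vapply(x, length, integer(1))), "bases\n")
  invisible(x)
}

#' @param track a `coverage_track`.
#' @rdname read_coverage
#' @export
write_coverage <- function(track, path) {
  lines <- character()
  for (cn in sort(names(track))) {
    v <- track[[cn]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      lines <- c(lines, paste(cn, starts[keep], ends[keep],
                              format_num(r$values[keep]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# mean / min depth over a 0-based half-open interval: Cov(x, y)
cov_mean <- function(track, chrom, start, end) {
  v <- track[[chrom]]
  if (is.null(v) || end > length(v)) stop("coverage interval off chromosome")
  mean(v[(start + 1L):end])
}
cov_min <- function(track, chrom, start, end) {
  v <- track[[chrom]]
  if (is.null(v) || end > length(v)) stop("coverage interval off chromosome")
  min(v[(start + 1L):end])
}

#' Read bisulfite methylation calls from a TSV
#'
#' Columns: chrom, 0-based cytosine position, strand, dinucleotide context,
#' methylated read count, total read count.
#'
#' @param path path to the methylation TSV (header line starting with `#`).
#' @return data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `methylated`, `total`.
#' @export
read_methylation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_methylation())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  m <- data.frame(chrom = f[, 1L], pos = as.integer(f[, 2L]), strand = f[, 3L],
                  context = f[, 4L], methylated = as.integer(f[, 5L]),
                  total = as.integer(f[, 6L]), stringsAsFactors = FALSE)
  if (any(m$methylated < 0L) || any(m$methylated > m$total)) {
    stop("methylated count must satisfy 0 <= methylated <= total")
  }
  m
}

empty_methylation <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             context = character(), methylated = integer(), total = integer(),
             stringsAsFactors = FALSE)
}

#' @param methylation methylation data.frame.
#' @rdname read_methylation
#' @export
write_methylation <- function(methylation, path) {
  lines <- "#chrom\tpos\tstrand\tcontext\tmethylated\ttotal"
  if (nrow(methylation) > 0L) {
    m <- methylation[order(methylation$chrom, methylation$pos,
                           methylation$strand), , drop = FALSE]
    lines <- c(lines, paste(m$chrom, m$pos, m$strand, m$context, m$methylated,
                            m$total, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog table
#'
#' Columns: gene_id, ortholog_id, ortholog_AS_event_count.  A gene with no
#' ortholog is simply absent from the table.
#'
#' @param path path to the ortholog TSV (header line starting with `#`).
#' @return data.frame with columns `gene_id`, `ortholog_id`,
#'   `ortholog_AS_event_count`.
#' @export
read_orthologs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), ortholog_id = character(),
                      ortholog_AS_event_count = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(gene_id = f[, 1L], ortholog_id = f[, 2L],
             ortholog_AS_event_count = as.integer(f[, 3L]),
             stringsAsFactors = FALSE)
}

#' Read / write a genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet-class] named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @param genome a `DNAStringSet`.
#' @rdname read_genome
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
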