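#' Cross-species conservation summary of alternatively spliced genes
#'
#' Joins the genes carrying AS events to a user-supplied ortholog table and
#' tabulates how many AS genes have an ortholog, how many of those
#' orthologs are themselves alternatively spliced, and how many ortholog
#' pairs have the same number of AS events in both species.  The equal-count
#' comparison pools all event kinds per gene; a per-kind breakdown of event
#' counts is emitted alongside.
#'
#' @param events event data.frame.
#' @param orthologs ortholog table ([read_orthologs()]): `gene_id`,
#'   `ortholog_id`, `ortholog_AS_event_count`.
#' @return list with `summary` (named counts: `as_genes`, `with_ortholog`,
#'   `with_as_ortholog`, `equal_event_count`) and `per_gene` (gene_id,
#'   n_events, per-kind columns, ortholog columns).
#' @export
conservation_summary <- function(events, orthologs) {
  dup <- duplicated(orthologs$gene_id)
  if (any(dup)) {
    clash <- vapply(unique(orthologs$gene_id[dup]), function(g) {
      length(unique(
        orthologs$ortholog_AS_event_count[orthologs$gene_id == g])) > 1L
    }, logical(1))
    if (any(clash)) {
      stop("conflicting ortholog AS event counts for gene ",
           unique(orthologs$gene_id[dup])[clash][1L])
    }
    orthologs <- orthologs[!dup, , drop = FALSE]
  }
  kinds <- c("IR", "CE", "ALT_DONOR", "ALT_ACCEPTOR", "AFE", "ALE")
  genes <- sort(unique(events$gene_id))
  per_gene <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  per_gene$n_events <- vapply(genes, function(g)
    sum(events$gene_id == g), integer(1))
  for (k in kinds) {
    per_gene[[paste0("n_", tolower(k))]] <- vapply(genes, function(g)
      sum(events$gene_id == g & events$kind == k), integer(1))
  }
  m <- match(per_gene$gene_id, orthologs$gene_id)
  per_gene$ortholog_id <- orthologs$ortholog_id[m]
  per_gene$ortholog_AS_event_count <- orthologs$ortholog_AS_event_count[m]
  has_orth <- !is.na(per_gene$ortholog_id)
  summary <- c(
    as_genes = length(genes),
    with_ortholog = sum(has_orth),
    with_as_ortholog = sum(has_orth &
                             per_gene$ortholog_AS_event_count > 0L,
                           na.rm = TRUE),
    equal_event_count = sum(has_orth &
                              per_gene$n_events ==
                                per_gene$ortholog_AS_event_count,
                            na.rm = TRUE))
  rownames(per_gene) <- NULL
  list(summary = summary, per_gene = per_gene)
}
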