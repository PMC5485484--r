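#' Assemble and cross-check the run summary
#'
#' Aggregates the outputs of every pipeline stage into a single summary
#' and asserts the cross-table identities that must hold among them
#' (miRNA totals, DE tallies, cleavage-site partition, unannotated-pool
#' plumbing). Violated identities abort with the identity named.
#'
#' @param cleaning named list of `cleaning_stats` (per library).
#' @param categories a [category_table()] data.frame.
#' @param conserved conserved miRNA calls (one row per distinct mature).
#' @param novel a [call_novel()] data.frame.
#' @param de a [call_de()] result.
#' @param hits a [call_cleavage()] data.frame.
#' @param degradome_summary optional [classify_degradome_tags()] summary.
#' @param unann_pool optional [unannotated_tags()] data.frame used for
#'   novel prediction (checked against the category table).
#' @return list of class `run_summary`.
#' @export
build_summary <- function(cleaning, categories, conserved, novel, de, hits,
                          degradome_summary = NULL, unann_pool = NULL) {
  for (stage in c("cleaning", "categories", "conserved", "novel", "de",
                  "hits")) {
    if (is.null(get(stage)) ||
        (is.data.frame(get(stage)) && is.null(dim(get(stage))))) {
      stop("missing stage output: ", stage)
    }
  }
  if (nrow(categories) == 0) stop("missing stage output: categories")

  n_conserved <- nrow(conserved)
  n_novel <- nrow(novel)
  n_total <- n_conserved + n_novel
  if (n_total == 0) stop("empty inputs: no miRNAs identified")

  tally <- de$tally
  if (tally["n_de"] != tally["n_up"] + tally["n_down"]) {
    stop("identity violated: n_de == n_up + n_down")
  }
  if (tally["n_sig"] > tally["n_de"]) {
    stop("identity violated: n_sig <= n_de")
  }

  arm_tally <- table(factor(novel$arm, levels = c("5p", "3p")))
  if (sum(arm_tally) != n_novel) {
    stop("identity violated: arm counts 5p + 3p == novel calls")
  }

  cat_counts <- table(factor(hits$category, levels = 0:4))
  if (sum(cat_counts) != nrow(hits)) {
    stop("identity violated: per-category sites sum to total sites")
  }

  for (lib in c("control", "treated")) {
    col <- paste0("unique_", lib)
    body <- categories[categories$category != "Total", col]
    tot <- categories[categories$category == "Total", col]
    if (sum(body) != tot) {
      stop("identity violated: category unique counts sum to Total (",
           lib, ")")
    }
  }
  if (!is.null(unann_pool)) {
    # the pool holds each unannotated tag once (pooled across libraries);
    # its size must match the unann per-library unique counts
    unann_row <- categories[categories$category == "unann", ]
    pool_n <- nrow(unann_pool)
    if (pool_n < max(unann_row$unique_control, unann_row$unique_treated) ||
        pool_n > unann_row$unique_control + unann_row$unique_treated) {
      stop("identity violated: unannotated pool size inconsistent with ",
           "the category table")
    }
  }

  structure(list(
    cleaning = cleaning,
    categories = categories,
    degradome_summary = degradome_summary,
    n_conserved = n_conserved, n_novel = n_novel, n_total = n_total,
    n_star_conserved = if ("has_star" %in% names(conserved))
      sum(conserved$has_star) else NA_integer_,
    n_star_novel = if (n_novel) sum(novel$has_star) else 0L,
    arm_tally = as.integer(arm_tally),
    precursor_len_mean = if (n_novel) mean(novel$precursor_length) else NA,
    mfe_mean = if (n_novel) mean(novel$mfe) else NA,
    de_tally = tally,
    n_targets = length(unique(hits$transcript)),
    n_sites = nrow(hits),
    site_categories = as.integer(cat_counts)
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("miRNAs: %d (%d conserved + %d novel; arms 5p/3p = %d/%d)\n",
              x$n_total, x$n_conserved, x$n_novel,
              x$arm_tally[1], x$arm_tally[2]))
  t <- x$de_tally
  cat(sprintf("DE: %d (%d up, %d down), significant %d\n",
              t["n_de"], t["n_up"], t["n_down"], t["n_sig"]))
  cat(sprintf("targets: %d genes, %d cleavage sites (categories 0-4: %s)\n",
              x$n_targets, x$n_sites,
              paste(x$site_categories, collapse = ", ")))
  invisible(x)
}

# Format a count with thousands separators (pretty variant only).
pretty_int <- function(x) formatC(x, big.mark = ",", format = "d")

#' Render summary tables to TSV
#'
#' Writes the sRNA category table and (when present) the degradome
#' summary in their two-columns-per-library layout. The machine variant
#' has plain integers and fixed decimal points; `pretty = TRUE` adds
#' thousands separators.
#'
#' @param summary a [build_summary()] result.
#' @param dir output directory.
#' @param pretty write the human-readable variant with comma separators.
#' @return named vector of written paths, invisibly.
#' @export
render_tables <- function(summary, dir, pretty = FALSE) {
  stopifnot(inherits(summary, "run_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    if (!pretty) return(df)
    for (col in names(df)) {
      if (is.numeric(df[[col]]) && !grepl("pct", col)) {
        df[[col]] <- pretty_int(df[[col]])
      }
    }
    df
  }
  paths <- c(categories = file.path(dir, "srna_categories.tsv"))
  write.table(fmt(summary$categories), paths[["categories"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(summary$degradome_summary)) {
    paths["degradome"] <- file.path(dir, "degradome_categories.tsv")
    write.table(fmt(summary$degradome_summary), paths[["degradome"]],
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Run the full pipeline on a synthetic experiment
#'
#' Orchestrates simulate -> preprocess -> annotate -> novel prediction ->
#' differential expression -> degradome -> summary on the outputs of the
#' synthetic-data generator.
#'
#' @param config a [simulation_config()].
#' @param workdir scratch directory for intermediate files (FASTQ/FASTA).
#' @param flank precursor window flank (nt).
#' @param verbose print stage progress.
#' @return list with all stage outputs: `ref`, `reads`, `cleaning`,
#'   `tags`, `annotation`, `categories`, `novel`, `de`, `degradome`,
#'   `duplexes`, `hits`, `summary`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         workdir = tempfile("srnadeg_run"), flank = 150,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating reference and libraries")
  ref <- make_reference(config)
  reads <- simulate_sra_reads(ref, workdir)
  deg <- simulate_degradome(ref, workdir)

  say("cleaning reads")
  cleaning <- lapply(reads$fastq, clean_reads, adapter = config$adapter_seq)
  tags <- collapse_tags(cleaning$control$reads, cleaning$treated$reads)

  say("annotating tags")
  annotation <- annotate_tags(tags, ref$known_matures, ref$noncoding,
                              ref$noncoding_family)
  categories <- category_table(annotation)
  unann <- unannotated_tags(annotation)

  say("predicting novel miRNAs")
  windows <- extract_precursors(unann, ref$transcripts, flank = flank)
  novel <- call_novel(windows, unann,
                      known_matures = annotation$conserved$sequence)

  say("differential expression")
  conserved <- annotation$conserved
  if (nrow(conserved)) {
    conserved$has_star <- flag_star_support(
      conserved$sequence, tags$sequence,
      tags$count_control + tags$count_treated)
  }
  # one expression row per identified mature (conserved calls + novel)
  expr_seqs <- unique(c(conserved$sequence, novel$mature))
  idx <- match(expr_seqs, tags$sequence)
  n1 <- cleaning$treated$stats$clean_reads
  n2 <- cleaning$control$stats$clean_reads
  expr <- ac_test(expr_seqs, tags$count_treated[idx], tags$count_control[idx],
                  n1, n2)
  de <- call_de(expr)

  say("degradome analysis")
  deg_ann <- classify_degradome_tags(deg$fasta[["control"]], ref$transcripts,
                                     ref$noncoding, ref$noncoding_family)
  mirnas <- setNames(expr_seqs, expr_seqs)
  duplexes <- align_mirna_targets(mirnas, ref$transcripts)
  hits <- call_cleavage(duplexes, deg_ann)

  say("building summary")
  summary <- build_summary(cleaning, categories, conserved, novel, de, hits,
                           degradome_summary = deg_ann$summary,
                           unann_pool = unann)
  list(ref = ref, reads = reads, cleaning = cleaning, tags = tags,
       annotation = annotation, categories = categories,
       conserved = conserved, novel = novel,
       de = de, expr = expr, degradome = deg_ann, duplexes = duplexes,
       hits = hits, summary = summary)
}
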