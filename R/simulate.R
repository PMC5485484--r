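#' Configuration for the synthetic small-RNA experiment
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' deliberately compact two-library drought-style experiment: two
#' conditions (control and treated), planted conserved and novel miRNA
#' hairpins embedded in a reference transcript ("unigene") set, noncoding
#' contaminants, adapter-carrying reads, and degradome tags concentrated
#' at miRNA-guided cleavage positions.
#'
#' @param n_transcripts number of reference transcripts.
#' @param transcript_len_range transcript length interval (nt).
#' @param n_conserved_mirnas planted miRNAs whose (mutated) matures are
#'   present in the known-mature database.
#' @param n_novel_mirnas planted miRNAs absent from the known database.
#' @param n_noncoding sequences per noncoding family (rRNA, tRNA, snRNA,
#'   snoRNA).
#' @param mature_len_range mature miRNA length interval; must lie within
#'   18-30 nt.
#' @param depth_per_library total reads per sRNA library.
#' @param de_fraction fraction of miRNAs with a nonzero true log2 fold
#'   change.
#' @param true_lfc_values pool of true log2 fold changes assigned to DE
#'   miRNAs (down-biased by default, as typical of severe-stress
#'   contrasts).
#' @param dispersion negative-binomial overdispersion of the count model;
#'   0 reduces to Poisson.
#' @param adapter_seq 3' adapter ligated to every read.
#' @param read_length raw read length (insert + adapter + fill).
#' @param mirna_fraction,noncoding_fraction,decoy_fraction expected share
#'   of the library made of miRNA reads, noncoding-derived reads, and
#'   decoys (too short/long, poly(A), low-quality); the remainder is
#'   random background.
#' @param star_fraction fraction of planted miRNAs whose star sequence
#'   also receives (low-abundance) reads.
#' @param degradome_depth tags per degradome library.
#' @param degradome_background number of background singleton tag
#'   positions per transcript in the degradome.
#' @param site_abundance_range tag count interval planted at each true
#'   cleavage site.
#' @param seed RNG seed; the same seed reproduces byte-identical outputs.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 45,
                              transcript_len_range = c(400, 800),
                              n_conserved_mirnas = 12,
                              n_novel_mirnas = 8,
                              n_noncoding = 4,
                              mature_len_range = c(20, 24),
                              depth_per_library = 50000,
                              de_fraction = 0.3,
                              true_lfc_values = c(-2, -2, -1.5, 1.5, 2),
                              dispersion = 0.02,
                              adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 50,
                              mirna_fraction = 0.35,
                              noncoding_fraction = 0.10,
                              decoy_fraction = 0.10,
                              star_fraction = 0.35,
                              degradome_depth = 6000,
                              degradome_background = 25,
                              site_abundance_range = c(30, 60),
                              seed = 20170611) {
  cfg <- as.list(environment())
  counts <- c("n_transcripts", "n_conserved_mirnas", "n_noncoding",
              "depth_per_library", "read_length", "degradome_depth")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("configuration error: '", f, "' must be a single positive count")
    }
  }
  if (cfg$n_novel_mirnas < 0) stop("configuration error: n_novel_mirnas < 0")
  if (cfg$mature_len_range[1] < 18 || cfg$mature_len_range[2] > 30 ||
      diff(cfg$mature_len_range) < 0) {
    stop("configuration error: mature_len_range must lie within 18-30 nt")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("configuration error: de_fraction must be in [0, 1]")
  }
  if (cfg$dispersion < 0) stop("configuration error: dispersion < 0")
  if (nchar(cfg$adapter_seq) < 6) {
    stop("configuration error: adapter_seq shorter than 6 nt")
  }
  if (cfg$transcript_len_range[1] < 200) {
    stop("configuration error: transcripts must be >= 200 nt to host ",
         "precursors and cleavage sites")
  }
  if (cfg$mirna_fraction + cfg$noncoding_fraction + cfg$decoy_fraction >= 1) {
    stop("configuration error: library composition fractions sum to >= 1")
  }
  if (2 * (cfg$n_conserved_mirnas + cfg$n_novel_mirnas) > cfg$n_transcripts) {
    stop("configuration error: need n_transcripts >= 2 * total miRNAs so ",
         "every miRNA gets a distinct host and a distinct target transcript")
  }
  structure(cfg, class = "simulation_config")
}

# Mature-length sampler: plant peaks at 21 and 24 nt (the canonical
# plant sRNA length modes) when the default range is in force.
sample_mature_len <- function(n, range) {
  lens <- seq(range[1], range[2])
  if (identical(as.integer(lens), 20:24)) {
    w <- c(0.12, 0.40, 0.13, 0.10, 0.25)
  } else {
    w <- rep(1, length(lens))
  }
  sample(lens, n, replace = TRUE, prob = w)
}

#' Build the synthetic reference bundle
#'
#' Constructs transcripts, planted miRNA hairpins, the known-mature
#' database, noncoding family databases and the ground truth. Hairpins are
#' built constructively - a 5' arm containing the mature (or its reverse
#' complement for 3p-arm miRNAs), an unstructured A/C loop of 12-18 nt,
#' and the mutated reverse complement of the arm - so every planted
#' precursor satisfies the hairpin acceptance criteria by construction.
#' Each miRNA also receives a target transcript carrying the reverse
#' complement of its mature at a recorded position, which defines the true
#' cleavage site (opposite mature positions 10-11).
#'
#' @param config a [simulation_config()].
#' @return a list of class `reference_bundle` with elements `transcripts`,
#'   `known_matures`, `noncoding` (each a named character vector),
#'   `noncoding_family` (family per noncoding sequence), `truth` (one row
#'   per planted miRNA) and `targets` (miRNA to transcript/cleavage map).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_mir <- config$n_conserved_mirnas + config$n_novel_mirnas
  if (2 * n_mir > config$n_transcripts) {
    stop("configuration error: need n_transcripts >= 2 * total miRNAs so ",
         "every miRNA gets a distinct host and a distinct target transcript")
  }

  mat_len <- sample_mature_len(n_mir, config$mature_len_range)
  mature <- random_dna(mat_len)
  arm <- sample(c("5p", "3p"), n_mir, replace = TRUE)
  class_lab <- rep(c("conserved", "novel"),
                   c(config$n_conserved_mirnas, config$n_novel_mirnas))
  mirna_id <- sprintf("%s-m%02d", ifelse(class_lab == "conserved", "c", "n"),
                      seq_len(n_mir))

  precursor <- character(n_mir)
  star_seq <- character(n_mir)
  for (i in seq_len(n_mir)) {
    a <- sample(10:20, 1)                      # pad between stem base and mature
    b <- sample(2:8, 1)                        # distance from mature to the loop
    L <- nchar(mature[i])
    core <- if (arm[i] == "5p") mature[i] else revcomp(mature[i])
    stem5 <- paste0(random_dna(a), core, random_dna(b))
    sl <- nchar(stem5)
    loop <- random_dna(sample(12:18, 1), letters = c("A", "C"))
    # for a 3p-arm mature the mature copy lives in stem3 (positions
    # b+1..b+L of rc(stem5)); keep injected mismatches off it so the
    # mature read still maps exactly to its host transcript
    banned <- if (arm[i] == "3p") (b + 1):(b + L) else integer(0)
    stem3 <- mutate_seq_at(revcomp(stem5), sample(0:2, 1),
                           setdiff(seq_len(sl), banned))
    precursor[i] <- paste0(stem5, loop, stem3)
    # star: the region pairing the mature on the opposite arm, with the
    # canonical 2-nt 3' offset, read from the finished precursor
    if (arm[i] == "5p") {
      p1 <- sl + nchar(loop) + (sl - (a + L) + 1)
      star_seq[i] <- substr(precursor[i], p1 + 2, p1 + 2 + L - 1)
    } else {
      star_seq[i] <- substr(precursor[i], a + 1 + 2, a + 2 + L)
    }
  }

  tx_len <- sample(seq(config$transcript_len_range[1],
                       config$transcript_len_range[2]),
                   config$n_transcripts, replace = TRUE)
  transcripts <- random_dna(tx_len)
  names(transcripts) <- sprintf("Unigene%04d", seq_len(config$n_transcripts))

  # embed precursors in distinct host transcripts, away from the edges
  host <- sample(config$n_transcripts, n_mir)
  host_pos <- integer(n_mir)
  for (i in seq_len(n_mir)) {
    tx <- transcripts[host[i]]
    plen <- nchar(precursor[i])
    if (nchar(tx) < plen + 100) {
      stop("configuration error: transcript too short to host a precursor")
    }
    s <- sample(seq(30, nchar(tx) - plen - 60), 1)
    substr(transcripts[host[i]], s, s + plen - 1) <- precursor[i]
    host_pos[i] <- s
  }

  # target transcripts: reverse complement of the mature, recorded
  # position; hosts and targets are disjoint so a cleavage site never
  # lands inside a precursor and every planted site is the lone strong
  # signal on its transcript
  target_tx <- integer(n_mir)
  cleavage_pos <- integer(n_mir)
  free <- setdiff(seq_len(config$n_transcripts), host)
  pool <- sample(free, n_mir)
  for (i in seq_len(n_mir)) {
    ti <- pool[i]
    tx <- transcripts[ti]
    L <- nchar(mature[i])
    s <- sample(seq(60, nchar(tx) - L - 60), 1)  # 0-based start of the site
    substr(transcripts[ti], s + 1, s + L) <- revcomp(mature[i])
    target_tx[i] <- ti
    cleavage_pos[i] <- s + L - 10                # tag 5' end, 0-based
  }

  # known-mature database: conserved matures with <= 2 substitutions
  kc <- which(class_lab == "conserved")
  known <- character(0)
  known_mm <- integer(0)
  if (length(kc)) {
    known_mm <- sample(0:2, length(kc), replace = TRUE)
    known <- vapply(seq_along(kc), function(k) {
      mutate_seq(mature[kc[k]], known_mm[k])
    }, character(1))
    names(known) <- sprintf("ath-miR%04d", seq_along(kc))
  }

  fams <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  nc_len <- sample(80:150, length(fams) * config$n_noncoding, replace = TRUE)
  noncoding <- random_dna(nc_len)
  noncoding_family <- rep(fams, each = config$n_noncoding)
  names(noncoding) <- sprintf("%s_%02d", noncoding_family,
                              sequence(rep(config$n_noncoding, length(fams))))

  # true log2 fold changes and abundance weights
  lfc <- rep(0, n_mir)
  n_de <- round(config$de_fraction * n_mir)
  if (n_de > 0) {
    de_idx <- sample(n_mir, n_de)
    lfc[de_idx] <- sample(config$true_lfc_values, n_de, replace = TRUE)
  }
  weight <- 10^runif(n_mir, 0, 2)

  has_star_reads <- rep(FALSE, n_mir)
  n_star <- round(config$star_fraction * n_mir)
  if (n_star > 0) has_star_reads[sample(n_mir, n_star)] <- TRUE

  truth <- data.frame(
    mirna_id = mirna_id, class = class_lab, mature = mature,
    mature_len = mat_len, precursor = precursor, arm = arm,
    star_seq = star_seq, has_star_reads = has_star_reads,
    host_transcript = names(transcripts)[host], host_pos = host_pos,
    known_id = NA_character_, known_mismatches = NA_integer_,
    true_lfc = lfc, is_de = abs(lfc) >= 1, weight = weight,
    stringsAsFactors = FALSE
  )
  if (length(kc)) {
    truth$known_id[kc] <- names(known)
    truth$known_mismatches[kc] <- known_mm
  }
  targets <- data.frame(
    mirna_id = mirna_id, transcript = names(transcripts)[target_tx],
    site_start = cleavage_pos - (mat_len - 10),  # 0-based duplex start
    cleavage_pos = cleavage_pos, stringsAsFactors = FALSE
  )

  structure(
    list(transcripts = transcripts, known_matures = known,
         noncoding = noncoding, noncoding_family = noncoding_family,
         truth = truth, targets = targets, config = config),
    class = "reference_bundle"
  )
}

#' Negative-binomial two-condition count model
#'
#' Draws per-miRNA raw counts for a control and a treated library from a
#' negative binomial with mean `mu` (control) and `mu * 2^lfc` (treated)
#' and dispersion `phi` (variance `mu + phi * mu^2`). `phi = 0` reduces
#' exactly to Poisson sampling.
#'
#' @param mu vector of control-library expected counts.
#' @param lfc vector of true log2 fold changes (recycled).
#' @param dispersion NB dispersion `phi >= 0`.
#' @return data.frame with `count_control` and `count_treated`.
#' @export
simulate_counts <- function(mu, lfc = 0, dispersion = 0.02) {
  stopifnot(all(mu >= 0), dispersion >= 0)
  n <- length(mu)
  lfc <- rep_len(lfc, n)
  draw <- function(m) {
    if (dispersion <= 1e-12) rpois(n, m) else rnbinom(n, mu = m, size = 1 / dispersion)
  }
  data.frame(count_control = draw(mu), count_treated = draw(mu * 2^lfc))
}

# One library worth of reads; returns list(seqs, quals, mirna_counts).
build_library <- function(ref, config, condition) {
  cfg <- config
  truth <- ref$truth
  n_mir <- nrow(truth)
  depth <- cfg$depth_per_library

  mu <- truth$weight / sum(truth$weight) * cfg$mirna_fraction * depth
  if (condition == "treated") mu <- mu * 2^truth$true_lfc
  counts <- if (cfg$dispersion <= 1e-12) rpois(n_mir, mu) else
    rnbinom(n_mir, mu = mu, size = 1 / cfg$dispersion)
  if (sum(counts) > depth) {
    stop("configuration error: realised miRNA reads exceed library depth; ",
         "increase depth_per_library or lower mirna_fraction")
  }

  inserts <- rep(truth$mature, counts)
  star_counts <- ifelse(truth$has_star_reads, sample(5:15, n_mir,
                                                     replace = TRUE), 0L)
  inserts <- c(inserts, rep(truth$star_seq, star_counts))
  qual_class <- rep("good", length(inserts))

  n_nc <- round(cfg$noncoding_fraction * depth)
  if (n_nc > 0) {
    src <- sample(length(ref$noncoding), n_nc, replace = TRUE)
    wlen <- sample(18:30, n_nc, replace = TRUE)
    nc_ins <- vapply(seq_len(n_nc), function(k) {
      sq <- ref$noncoding[src[k]]
      w <- min(wlen[k], nchar(sq))
      st <- sample(nchar(sq) - w + 1, 1)
      substr(sq, st, st + w - 1)
    }, character(1))
    inserts <- c(inserts, nc_ins)
    qual_class <- c(qual_class, rep("good", n_nc))
  }

  n_decoy <- round(cfg$decoy_fraction * depth)
  per <- n_decoy %/% 4
  if (per > 0) {
    short_ins <- random_dna(sample(10:17, per, replace = TRUE))
    long_ins <- random_dna(sample(31:35, per, replace = TRUE))
    polya_ins <- paste0(random_dna(sample(8:12, per, replace = TRUE)),
                        strrep("A", 12))
    lowq_ins <- random_dna(sample(18:30, per, replace = TRUE))
    inserts <- c(inserts, short_ins, long_ins, polya_ins, lowq_ins)
    qual_class <- c(qual_class, rep(c("good", "good", "good", "low"),
                                    each = per))
  }

  n_bg <- depth - length(inserts)
  if (n_bg > 0) {
    inserts <- c(inserts, random_dna(sample(18:30, n_bg, replace = TRUE)))
    qual_class <- c(qual_class, rep("good", n_bg))
  }

  reads <- paste0(inserts, cfg$adapter_seq)
  fill_needed <- pmax(0, cfg$read_length - nchar(reads))
  fill <- vapply(fill_needed, function(k) {
    if (k == 0) "" else paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = "")
  }, character(1))
  reads <- substr(paste0(reads, fill), 1, cfg$read_length)

  qual_chr <- function(len, lo, hi) {
    vapply(len, function(k) {
      intToUtf8(sample(lo:hi, k, replace = TRUE) + 33L)
    }, character(1))
  }
  quals <- character(length(reads))
  good <- qual_class == "good"
  quals[good] <- qual_chr(nchar(reads[good]), 32, 40)
  quals[!good] <- qual_chr(nchar(reads[!good]), 8, 16)

  ord <- sample(length(reads))
  list(seqs = reads[ord], quals = quals[ord], mirna_counts = counts)
}

#' Simulate the two small-RNA FASTQ libraries
#'
#' Draws per-miRNA counts from the negative-binomial two-condition model,
#' assembles reads (insert + 3' adapter + random fill to the configured
#' read length, Phred+33 qualities), adds noncoding-derived reads, random
#' background and decoys (too-short and too-long inserts, poly(A) reads,
#' low-quality reads), and writes one FASTQ per condition.
#'
#' @param ref a [make_reference()] bundle.
#' @param outdir directory for `control.fastq` and `treated.fastq`.
#' @return list with `fastq` (named file paths) and `truth_counts` (one
#'   row per planted miRNA: realised counts per library).
#' @export
simulate_sra_reads <- function(ref, outdir) {
  stopifnot(inherits(ref, "reference_bundle"))
  cfg <- ref$config
  if (cfg$depth_per_library <= 0) stop("configuration error: zero depth")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)

  paths <- c(control = file.path(outdir, "control.fastq"),
             treated = file.path(outdir, "treated.fastq"))
  truth_counts <- data.frame(mirna_id = ref$truth$mirna_id)
  for (cond in c("control", "treated")) {
    lib <- build_library(ref, cfg, cond)
    ids <- sprintf("%s_read%06d", cond, seq_along(lib$seqs))
    write_fastq(ids, lib$seqs, lib$quals, paths[[cond]])
    truth_counts[[paste0("count_", cond)]] <- lib$mirna_counts
  }
  list(fastq = paths, truth_counts = truth_counts)
}

#' Simulate degradome tag libraries
#'
#' For every true target, plants 20-21 nt tags whose 5' ends sit exactly
#' at the recorded cleavage position (opposite mature positions 10-11)
#' with abundance drawn from `site_abundance_range`, guaranteed to exceed
#' any other position on that transcript; adds uniform background
#' singleton tags, poly(N) decoys and noncoding-derived tags; writes one
#' FASTA per condition with one record per tag copy.
#'
#' @param ref a [make_reference()] bundle.
#' @param outdir directory for `degradome_control.fasta` /
#'   `degradome_treated.fasta`.
#' @param background_per_transcript number of background singleton
#'   positions per transcript; `NULL` uses the configured default.
#' @return list with `fasta` (named paths) and `targets` (the true site
#'   map).
#' @export
simulate_degradome <- function(ref, outdir, background_per_transcript = NULL) {
  stopifnot(inherits(ref, "reference_bundle"))
  if (nrow(ref$targets) == 0) stop("configuration error: no targets planted")
  cfg <- ref$config
  bg <- if (is.null(background_per_transcript)) cfg$degradome_background else
    background_per_transcript
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 2L)

  paths <- c(control = file.path(outdir, "degradome_control.fasta"),
             treated = file.path(outdir, "degradome_treated.fasta"))
  for (cond in c("control", "treated")) {
    tags <- character(0)
    # planted cleavage-site tags
    for (k in seq_len(nrow(ref$targets))) {
      tx <- ref$transcripts[ref$targets$transcript[k]]
      c0 <- ref$targets$cleavage_pos[k]
      n_site <- sample(seq(cfg$site_abundance_range[1],
                           cfg$site_abundance_range[2]), 1)
      tlen <- sample(20:21, n_site, replace = TRUE)
      tlen <- pmin(tlen, nchar(tx) - c0)
      tags <- c(tags, substring(tx, c0 + 1, c0 + tlen))
    }
    # uniform background singletons
    if (bg > 0) {
      for (ti in seq_along(ref$transcripts)) {
        tx <- ref$transcripts[ti]
        pos <- sample(0:(nchar(tx) - 21), bg)
        tags <- c(tags, substring(tx, pos + 1, pos + 20))
      }
    }
    # decoys: poly(N) and noncoding windows and random 'other' tags
    n_polyn <- 40
    polyn <- vapply(seq_len(n_polyn), function(k) {
      s <- random_dna(20)
      substr(s, 5, 5 + sample(5:10, 1)) <- strrep("N", sample(6, 1) + 5)
      substr(s, 1, 20)
    }, character(1))
    nc_src <- sample(length(ref$noncoding), 60, replace = TRUE)
    nc_tags <- vapply(nc_src, function(i) {
      sq <- ref$noncoding[i]
      st <- sample(nchar(sq) - 20 + 1, 1)
      substr(sq, st, st + 19)
    }, character(1))
    other <- random_dna(rep(20, max(0, cfg$degradome_depth - length(tags) -
                                      n_polyn - length(nc_tags))))
    tags <- c(tags, polyn, nc_tags, other)
    tags <- sample(tags)
    names(tags) <- sprintf("%s_tag%06d", cond, seq_along(tags))
    writeLines(paste0(">", names(tags), "\n", tags), paths[[cond]])
  }
  list(fasta = paths, targets = ref$targets)
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' Builds replicate Ct values for a set of assayed genes and an endogenous
#' reference in two conditions, such that the expected 2^-ddCt fold of
#' each gene equals `2^lfc`.
#'
#' @param gene_ids character vector of assayed gene ids.
#' @param lfc true log2 fold changes (treated vs control), recycled.
#' @param n_rep replicates per condition (>= 2).
#' @param noise_sd Ct measurement noise (cycles).
#' @param reference_id id of the endogenous control row.
#' @param seed RNG seed.
#' @return a Ct table data.frame (gene, role, condition, replicate, ct).
#' @export
simulate_ct_table <- function(gene_ids, lfc = 0, n_rep = 3, noise_sd = 0.15,
                              reference_id = "U6", seed = 1) {
  stopifnot(n_rep >= 2)
  set.seed(seed)
  lfc <- rep_len(lfc, length(gene_ids))
  rows <- list()
  for (cond in c("control", "treated")) {
    rows[[length(rows) + 1]] <- data.frame(
      gene = reference_id, role = "reference", condition = cond,
      replicate = seq_len(n_rep),
      ct = 20 + rnorm(n_rep, 0, noise_sd), stringsAsFactors = FALSE
    )
    for (g in seq_along(gene_ids)) {
      base_ct <- 25
      shift <- if (cond == "treated") -lfc[g] else 0
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene_ids[g], role = "target", condition = cond,
        replicate = seq_len(n_rep),
        ct = base_ct + shift + rnorm(n_rep, 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write/read a plain-text key=value configuration file
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `path` invisibly (write) or a [simulation_config()] (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  vals <- vapply(config, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  do.call(simulation_config, vals)
}
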