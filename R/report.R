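#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `digits` decimals
#' (0 for summary-table cells, 1 for small in-text percentages).
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @param digits decimal places.
#' @return numeric percentage.
#' @export
percent <- function(numerator, denominator, digits = 0) {
  if (any(denominator <= 0)) stop("zero denominator", call. = FALSE)
  round_half_up(100 * numerator / denominator, digits)
}

SUMMARY_ROWS <- c("all", "forward", "reverse", "protein_coding", "leaderless",
                  "leadered", "known_rna", "novel", "intergenic_novel",
                  "antisense", "internal")

#' Classification summary table
#'
#' Per-replicon counts of all TSSs, by strand, and by class, with the
#' block structure of a primary-TSS classification table:
#' protein-coding (leaderless + leadered), known RNAs, and novel
#' (intergenic + antisense + internal).  Percentages use the block totals
#' as denominators: strand and major-class rows are percentages of all
#' TSSs, leaderless/leadered of the protein-coding total, and the novel
#' subclasses of the novel total.
#'
#' @param classified output of [classify_tss()].
#' @param replicons replicon names (default: those present).
#' @return data.frame of class `summary_table` with one row per summary
#'   class, one column per replicon, plus `total` and `percent`.
#' @export
summarize_tss <- function(classified, replicons = NULL) {
  replicons <- replicons %||% sort(unique(classified$replicon))
  if (!all(classified$replicon %in% replicons)) {
    stop("classified table contains replicons absent from the replicon list",
         call. = FALSE)
  }
  count <- function(sel) {
    vapply(replicons, function(r) {
      sum(sel & classified$replicon == r)
    }, numeric(1))
  }
  cls <- classified$primary_class
  rows <- list(
    all = count(rep(TRUE, nrow(classified))),
    forward = count(classified$strand == "+"),
    reverse = count(classified$strand == "-"),
    protein_coding = count(cls %in% c("leaderless", "leadered")),
    leaderless = count(cls == "leaderless"),
    leadered = count(cls == "leadered"),
    known_rna = count(cls == "known_rna"),
    novel = count(cls %in% c("intergenic_novel", "antisense", "internal")),
    intergenic_novel = count(cls == "intergenic_novel"),
    antisense = count(cls == "antisense"),
    internal = count(cls == "internal"))
  m <- do.call(rbind, rows)
  colnames(m) <- replicons
  total <- rowSums(m)
  denom <- c(all = NA, forward = total[["all"]], reverse = total[["all"]],
             protein_coding = total[["all"]],
             leaderless = total[["protein_coding"]],
             leadered = total[["protein_coding"]],
             known_rna = total[["all"]], novel = total[["all"]],
             intergenic_novel = total[["novel"]],
             antisense = total[["novel"]], internal = total[["novel"]])
  pct <- ifelse(is.na(denom) | denom == 0, NA,
                round_half_up(100 * total / denom, 0))
  out <- data.frame(class = SUMMARY_ROWS, m, total = total, percent = pct,
                    check.names = FALSE, row.names = NULL)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Check the partition identities of a summary table
#'
#' forward + reverse = all; leaderless + leadered = protein-coding;
#' intergenic + antisense + internal = novel; protein-coding + known RNAs
#' + novel = all — for the totals and within every replicon column.
#'
#' @param st a [summarize_tss()] table.
#' @return `TRUE` (invisibly) or an error describing the broken identity.
#' @export
check_summary_invariants <- function(st) {
  g <- function(cl) {
    unlist(st[st$class == cl, !(names(st) %in% c("class", "percent")),
              drop = FALSE])
  }
  stopifnot(all(g("forward") + g("reverse") == g("all")))
  stopifnot(all(g("leaderless") + g("leadered") == g("protein_coding")))
  stopifnot(all(g("intergenic_novel") + g("antisense") + g("internal") ==
                  g("novel")))
  stopifnot(all(g("protein_coding") + g("known_rna") + g("novel") == g("all")))
  invisible(TRUE)
}

#' Published per-replicon classification counts
#'
#' The per-replicon TSS classification counts of a published
#' *Haloferax volcanii* dRNA-Seq study (main chromosome and the pHV1,
#' pHV3 and pHV4 replicons), shipped as a worked-example input for the
#' summary-table arithmetic.
#'
#' @return data.frame with `class` and one count column per replicon.
#' @export
class_counts_example <- function() {
  read_tsv(system.file("extdata", "tss_class_counts.tsv",
                       package = "haloTSS"))
}

#' Run the whole analysis end to end
#'
#' Generates (or takes) a fixture, then executes TSS calling,
#' classification, promoter refinement and classification, the UTR /
#' start-codon / decile analyses, the uORF scan, the sense/antisense
#' reciprocity analysis and the classification summary.  When `outdir` is
#' given, stage outputs are written as TSVs together with a manifest of
#' files and parameters.  Stage failures are re-thrown with the stage
#' name.
#'
#' @param config a [synth_config()] (ignored when `fixture` is given,
#'   except for calling parameters).
#' @param outdir optional output directory.
#' @param fixture optional pre-built fixture (a `synth_genome`-shaped list
#'   with `genome`, and optionally `truth`/`decoys`, plus `coverage`), e.g.
#'   from [read_fixture()].
#' @param min_height,step_factor,min_enrichment caller parameters, see
#'   [call_tss()].
#' @param refine_p promoter-refinement match p-value.
#' @param quiet suppress progress messages.
#' @return list with all stage results.
#' @export
run_pipeline <- function(config = synth_config(), outdir = NULL,
                         fixture = NULL, min_height = 5, step_factor = 2,
                         min_enrichment = 2.5, refine_p = 0.001,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (is.null(fixture)) {
    say("simulating fixture (seed ", config$seed, ")")
    sim <- stage("simulate", generate_genome(config))
    coverage <- stage("simulate", simulate_all_coverage(sim))
    fixture <- list(genome = sim$genome, truth = sim$truth,
                    decoys = sim$decoys, coverage = coverage)
  }
  genome <- fixture$genome

  say("calling TSSs")
  consensus <- stage("calling", call_tss_consensus(
    fixture$coverage, min_height = min_height, step_factor = step_factor,
    min_enrichment = min_enrichment))
  consensus$tss_id <- sprintf("TSS%05d", seq_len(nrow(consensus)))
  say("  ", nrow(consensus), " consensus TSSs (",
      sum(consensus$support >= 2), " in >=2 replicates)")

  say("classifying TSSs")
  classified <- stage("classify", {
    cl <- classify_tss(consensus, genome)
    add_downstream_flags(cl, genome)
  })

  say("refining promoter model")
  promoter <- stage("promoter", {
    ups <- extract_upstream(genome, classified)
    q <- genome_background(genome)
    refinement <- refine_pwm(ups, q, p = refine_p)
    calls <- classify_promoters(refinement$pwm, ups)
    logo <- logo_matrix(substr(ups$seq[refinement$positives],
                               refinement$offsets,
                               refinement$offsets + refinement$pwm$width - 1),
                        q)
    list(upstream = ups, refinement = refinement, calls = calls, logo = logo)
  })
  classified$promoter_class <-
    promoter$calls$promoter_class[match(classified$tss_id,
                                        promoter$calls$tss_id)]
  classified$promoter_class[is.na(classified$promoter_class)] <- "none"

  say("running downstream analyses")
  analyses <- stage("analyses", {
    pc_classes <- c("leaderless", "leadered")
    novel_classes <- c("intergenic_novel", "antisense", "internal")
    pairs <- pair_sense_antisense(classified)
    list(
      utr = utr_histograms(classified),
      deciles_protein = expression_deciles(classified, pc_classes),
      deciles_novel = expression_deciles(classified, novel_classes),
      start_codons = start_codon_summary(classified, genome),
      itss_deciles = decile_distribution(classified, genome, "internal"),
      atss_deciles = decile_distribution(classified, genome, "antisense"),
      multi_tss = find_multi_tss(classified),
      uorfs = scan_long_utr_uorfs(classified, genome),
      small_protein_tss = count_small_protein_tss(classified, genome),
      pairs = pairs,
      reciprocity = if (nrow(pairs) >= 2) reciprocity_stats(pairs) else NULL,
      transposase = category_overlap(classified, genome, "transposase"))
  })

  say("summarizing")
  summary <- stage("summarize", {
    st <- summarize_tss(classified)
    check_summary_invariants(st)
    st
  })

  result <- list(fixture = fixture, consensus = consensus,
                 classified = classified, promoter = promoter,
                 analyses = analyses, summary = summary,
                 params = list(min_height = min_height,
                               step_factor = step_factor,
                               min_enrichment = min_enrichment,
                               refine_p = refine_p,
                               seed = if (!is.null(config)) config$seed else NA))

  if (!is.null(outdir)) {
    stage("write", write_pipeline_outputs(result, outdir))
  }
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    files <<- c(files, name)
  }
  put(result$consensus, "tss_consensus.tsv")
  put(result$classified, "tss_classified.tsv")
  put(result$promoter$calls, "promoter_calls.tsv")
  pwm <- result$promoter$refinement$pwm
  put(data.frame(base = rownames(pwm$log_odds), pwm$log_odds,
                 check.names = FALSE), "promoter_pwm_logodds.tsv")
  put(data.frame(base = rownames(pwm$counts), pwm$counts,
                 check.names = FALSE), "promoter_pwm_counts.tsv")
  put(data.frame(base = rownames(result$promoter$logo$contributions),
                 result$promoter$logo$contributions, check.names = FALSE),
      "promoter_logo.tsv")
  put(result$summary, "summary_table.tsv")
  put(result$analyses$uorfs, "uorfs.tsv")
  put(result$analyses$pairs, "sense_antisense_pairs.tsv")
  put(result$analyses$multi_tss, "multi_tss_genes.tsv")
  manifest <- data.frame(
    file = files,
    bytes = vapply(file.path(outdir, files), function(f)
      as.numeric(file.info(f)$size), numeric(1)),
    row.names = NULL)
  attr(manifest, "params") <- result$params
  p <- file.path(outdir, "manifest.tsv")
  pkg_ver <- as.character(utils::packageVersion("haloTSS"))
  header <- c(paste0("# haloTSS ", pkg_ver),
              paste0("# ", names(result$params), " = ",
                     unlist(lapply(result$params, format))))
  writeLines(c(header, paste(c("file", "bytes"), collapse = "\t")), p)
  utils::write.table(manifest, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(manifest)
}
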