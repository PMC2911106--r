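#' Simulation configuration
#'
#' Parameters of the synthetic-genome generator. Lengths are drawn from
#' log-normal distributions (positive, heavy right tails, as in real genomic
#' length data), with separate 3'/5' UTR parameters per conservation class
#' so that core genes carry shorter regulatory regions than metazoan ones.
#' Planted, recoverable effects are expressed per origin class through
#' `class_effects`: `igr5_scale` multiplies the intergenic gap facing a
#' gene's 5' end, and `utr3_left_truncation_percentile` re-draws the gene's
#' 3' UTR conditional on exceeding that percentile of its base distribution
#' (under-representation of short 3' UTRs). With `class_effects` empty the
#' generator is a null: class and genome-wide length distributions are
#' statistically indistinguishable.
#'
#' @param seed integer seed; identical configs give byte-identical output.
#' @param n_genes,n_chromosomes genome size.
#' @param spacing_meanlog,spacing_sdlog log-normal intergenic gap (bp).
#' @param exon_count_range inclusive range of exon counts per transcript.
#' @param cds_exon_meanlog,cds_exon_sdlog per-exon coding length (bp).
#' @param intron_meanlog,intron_sdlog intron length (bp).
#' @param utr3_dist,utr5_dist named lists (`core`, `metazoan`, `other`) of
#'   `c(meanlog, sdlog)` for UTR lengths (bp).
#' @param frac_core,frac_metazoan conservation class proportions (the
#'   remainder is `other`).
#' @param origin_probs named origin-class probabilities (must sum to 1).
#' @param class_effects named list: origin class -> list(igr5_scale,
#'   utr3_left_truncation_percentile).
#' @param conservation_igr5_scale named multipliers (`core`, `metazoan`,
#'   `other`) on the 5'-facing intergenic gap, planting the conserved
#'   core-shorter-than-metazoan relationship (all 1 = null).
#' @param operon_fraction target fraction of genes inside operons.
#' @param alt_splice_prob probability a gene gets a second isoform with a
#'   shortened 3' UTR.
#' @param n_unicellular,n_plant,n_animal phylogenetic panel composition
#'   (defaults 4/2/20, a 26-taxon panel).
#' @param timepoints number of expression time points (first is pre-MZT).
#' @param mzt_index index of the last pre-transition time point.
#' @param decay_fold maternal post-transition decay factor (>= 3).
#' @param expr_meanlog2,expr_sdlog2 log2 expression level distribution.
#' @param noise_sd_log2 multiplicative log2 noise on the time course.
#' @param presence_call abundance threshold for presence.
#' @param ortholog_fraction fraction of usable genes in the 1:1:1 tables.
#' @param ortholog_rank_noise sd of the Gaussian rank perturbation between
#'   ortholog genomes (0 = ranks preserved exactly).
#' @param maternal_overlap probability a maternal gene is maternal in the
#'   partner species too.
#' @param maternal_rank_shift planted downward shift of partner-species
#'   ranks for maternal pairs of the first species pair (0 = null).
#' @param rnai_no_phenotype_fraction fraction of maternal genes with no
#'   RNAi phenotype.
#' @param rnai_effect strength of the association between having a
#'   phenotype and 5' IGR length (0 = null).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 500L, n_chromosomes = 2L,
                       spacing_meanlog = log(1000), spacing_sdlog = 0.8,
                       exon_count_range = c(1L, 4L),
                       cds_exon_meanlog = log(250), cds_exon_sdlog = 0.5,
                       intron_meanlog = log(200), intron_sdlog = 0.6,
                       utr3_dist = list(core = c(log(150), 0.7),
                                        metazoan = c(log(350), 0.7),
                                        other = c(log(250), 0.7)),
                       utr5_dist = list(core = c(log(80), 0.6),
                                        metazoan = c(log(150), 0.6),
                                        other = c(log(120), 0.6)),
                       frac_core = 0.30, frac_metazoan = 0.50,
                       origin_probs = c(strict_maternal = 0.11,
                                        mostly_maternal = 0.05,
                                        maternal_zygotic = 0.30,
                                        mostly_zygotic = 0.05,
                                        strict_zygotic = 0.04,
                                        unclassified = 0.45),
                       class_effects = list(),
                       conservation_igr5_scale = c(core = 1, metazoan = 1,
                                                   other = 1),
                       operon_fraction = 0,
                       alt_splice_prob = 0.15,
                       n_unicellular = 4L, n_plant = 2L, n_animal = 20L,
                       timepoints = 4L, mzt_index = 1L,
                       decay_fold = 8, expr_meanlog2 = 6, expr_sdlog2 = 1,
                       noise_sd_log2 = 0.2, presence_call = 1,
                       ortholog_fraction = 0.8, ortholog_rank_noise = 0,
                       maternal_overlap = 0.7, maternal_rank_shift = 0,
                       rnai_no_phenotype_fraction = 0.165, rnai_effect = 0) {
  stopifnot(n_genes >= 2L, n_chromosomes >= 1L,
            frac_core >= 0, frac_metazoan >= 0, frac_core + frac_metazoan <= 1,
            abs(sum(origin_probs) - 1) < 1e-8, decay_fold >= 3,
            operon_fraction >= 0, operon_fraction < 1,
            ortholog_fraction > 0, ortholog_fraction <= 1,
            timepoints >= 2L, mzt_index >= 1L, mzt_index < timepoints)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

class_effect <- function(config, origin, field, default) {
  eff <- config$class_effects[[origin]]
  if (is.null(eff) || is.null(eff[[field]])) default else eff[[field]]
}

draw_utr <- function(n, params, trunc_percentile = NULL) {
  if (is.null(trunc_percentile)) {
    len <- rlnorm(n, params[1], params[2])
  } else {
    u <- runif(n, trunc_percentile / 100, 1)
    len <- qlnorm(u, params[1], params[2])
  }
  pmax(0L, as.integer(round(len)))
}

# exon/CDS layout of one transcript on the + strand starting at gs;
# returns list(exons, cds) of 0-based half-open tibether rows
layout_transcript <- function(gs, u5, cds_lens, intron_lens, u3) {
  k <- length(cds_lens)
  ex_len <- cds_lens
  ex_len[1] <- ex_len[1] + u5
  ex_len[k] <- ex_len[k] + u3
  starts <- integer(k)
  ends <- integer(k)
  cur <- gs
  for (i in seq_len(k)) {
    starts[i] <- cur
    ends[i] <- cur + ex_len[i]
    cur <- ends[i] + if (i < k) intron_lens[i] else 0L
  }
  cds_s <- starts
  cds_e <- ends
  cds_s[1] <- starts[1] + u5
  cds_e[k] <- ends[k] - u3
  keep <- cds_s < cds_e
  list(ex_start = starts, ex_end = ends,
       cds_start = cds_s[keep], cds_end = cds_e[keep])
}

reflect_intervals <- function(start, end, lo, hi) {
  list(start = rev(lo + hi - end), end = rev(lo + hi - start))
}

#' Simulate a synthetic genome annotation with planted effects
#'
#' Lays genes down sequentially along each chromosome with log-normal
#' intergenic gaps; each gene first receives a conservation and an origin
#' class, then its structure (exon count, intron, CDS and UTR lengths) is
#' drawn from class-conditional distributions with the configured planted
#' effects applied. Real coordinates are produced (and can be written to
#' GFF3), so the annotation parser and interval engine are exercised end to
#' end. Runs of consecutive genes can be grouped into operons (forced to
#' the + strand with short internal gaps). Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (a [genome_annotation()]), `operons`
#'   (tibble `gene_id`, `operon_id`, `position`), and `truth` (tibble
#'   `gene_id`, `origin_class`, `conservation_class`, `timecourse_class`,
#'   `all_maternal`).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  cons <- sample(c("core", "metazoan", "other"), n, replace = TRUE,
                 prob = c(config$frac_core, config$frac_metazoan,
                          1 - config$frac_core - config$frac_metazoan))
  origin <- sample(names(config$origin_probs), n, replace = TRUE,
                   prob = config$origin_probs)
  chrom <- sprintf("chr%d", rep(seq_len(config$n_chromosomes), length.out = n,
                                each = ceiling(n / config$n_chromosomes)))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # operon runs: consecutive genes on one chromosome, + strand, tight gaps
  operon_id <- rep(NA_character_, n)
  operon_pos <- rep(NA_integer_, n)
  if (config$operon_fraction > 0) {
    op_count <- 0L
    i <- 1L
    while (i <= n) {
      if (is.na(operon_id[i]) && runif(1) < config$operon_fraction / 3) {
        size <- sample(2:4, 1L)
        members <- i:min(n, i + size - 1L)
        members <- members[chrom[members] == chrom[i]]
        if (length(members) >= 2L) {
          op_count <- op_count + 1L
          operon_id[members] <- sprintf("op%03d", op_count)
          operon_pos[members] <- seq_along(members)
          strand[members] <- "+"
          i <- max(members) + 1L
          next
        }
      }
      i <- i + 1L
    }
  }

  # per-gene structure draws
  n_ex <- sample(seq(config$exon_count_range[1], config$exon_count_range[2]),
                 n, replace = TRUE)
  utr3 <- integer(n)
  utr5 <- integer(n)
  for (cc in c("core", "metazoan", "other")) {
    for (oc in unique(origin)) {
      sel <- cons == cc & origin == oc
      if (!any(sel)) next
      tp <- class_effect(config, oc, "utr3_left_truncation_percentile", NULL)
      utr3[sel] <- draw_utr(sum(sel), config$utr3_dist[[cc]], tp)
      utr5[sel] <- draw_utr(sum(sel), config$utr5_dist[[cc]], NULL)
    }
  }

  tx_rows <- list()
  ex_rows <- list()
  cds_rows <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cursor <- 1000L
    prev_strand <- NULL
    for (j in seq_along(idx)) {
      i <- idx[j]
      in_operon_run <- !is.na(operon_id[i]) && !is.na(operon_pos[i]) &&
        operon_pos[i] > 1L
      if (in_operon_run) {
        gap <- rlnorm(1, log(100), 0.3)
      } else {
        gap <- rlnorm(1, config$spacing_meanlog, config$spacing_sdlog)
        scale <- 1
        if (strand[i] == "+") {
          scale <- scale * class_effect(config, origin[i], "igr5_scale", 1) *
            config$conservation_igr5_scale[[cons[i]]]
        }
        if (!is.null(prev_strand) && prev_strand == "-") {
          prev_i <- idx[j - 1L]
          scale <- scale * class_effect(config, origin[prev_i], "igr5_scale", 1) *
            config$conservation_igr5_scale[[cons[prev_i]]]
        }
        gap <- gap * scale
      }
      gap <- as.integer(round(gap))
      if (gap < 0L) abort("infeasible config: intergenic gap collapsed below 0")
      gap <- max(1L, gap)
      gs <- cursor + gap

      cds_lens <- pmax(9L, as.integer(round(
        rlnorm(n_ex[i], config$cds_exon_meanlog, config$cds_exon_sdlog))))
      intron_lens <- if (n_ex[i] > 1L) {
        pmax(20L, as.integer(round(
          rlnorm(n_ex[i] - 1L, config$intron_meanlog, config$intron_sdlog))))
      } else integer(0)
      iso_u3 <- utr3[i]
      isoforms <- list(iso_u3)
      if (runif(1) < config$alt_splice_prob && iso_u3 > 10L) {
        isoforms <- c(isoforms, as.integer(round(iso_u3 * runif(1, 0.3, 0.9))))
      }
      gene_end <- gs
      for (v in seq_along(isoforms)) {
        lay <- layout_transcript(gs, utr5[i], cds_lens, intron_lens,
                                 isoforms[[v]])
        if (strand[i] == "-") {
          lo <- min(lay$ex_start)
          hi <- max(lay$ex_end)
          ex <- reflect_intervals(lay$ex_start, lay$ex_end, lo, hi)
          cd <- reflect_intervals(lay$cds_start, lay$cds_end, lo, hi)
          lay$ex_start <- ex$start
          lay$ex_end <- ex$end
          lay$cds_start <- cd$start
          lay$cds_end <- cd$end
        }
        tid <- sprintf("%s.t%d", gene_id[i], v)
        tx_rows[[length(tx_rows) + 1L]] <-
          tibble(transcript_id = tid, gene_id = gene_id[i])
        ex_rows[[length(ex_rows) + 1L]] <-
          tibble(transcript_id = tid, start = lay$ex_start, end = lay$ex_end)
        cds_rows[[length(cds_rows) + 1L]] <-
          tibble(transcript_id = tid, start = lay$cds_start, end = lay$cds_end)
        gene_end <- max(gene_end, max(lay$ex_end))
      }
      cursor <- gene_end
      prev_strand <- strand[i]
    }
  }

  genes <- tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                  operon_id = operon_id, operon_position = operon_pos)
  annotation <- genome_annotation(genes, bind_rows(tx_rows),
                                  bind_rows(ex_rows), bind_rows(cds_rows))
  in_op <- !is.na(operon_id)
  operons <- tibble(gene_id = gene_id[in_op],
                    operon_id = operon_id[in_op],
                    position = operon_pos[in_op])
  timecourse_class <- dplyr::recode(origin,
                                    mostly_maternal = "strict_maternal",
                                    mostly_zygotic = "strict_zygotic")
  truth <- tibble(gene_id = gene_id,
                  origin_class = factor(origin, levels = origin_levels),
                  conservation_class = cons,
                  timecourse_class = factor(timecourse_class,
                                            levels = origin_levels),
                  all_maternal = origin %in% c("strict_maternal",
                                               "mostly_maternal",
                                               "maternal_zygotic"))
  list(annotation = annotation, operons = operons, truth = truth)
}

#' Simulate phylogenetic presence/absence profiles
#'
#' Builds a presence/absence matrix over a panel of unicellular, plant and
#' animal taxa consistent with each gene's true conservation class, so the
#' conservation classifier recovers the truth exactly.
#'
#' @param truth truth table from [simulate_genome()].
#' @param config a [sim_config()].
#' @return list with `profiles` (tibble, `gene_id` x taxon 0/1) and
#'   `taxon_kinds` (tibble `taxon`, `kind`).
#' @export
simulate_phylo_profiles <- function(truth, config = sim_config()) {
  with_seed_if(config$seed + 1L, {
    taxa <- c(sprintf("unicell_%02d", seq_len(config$n_unicellular)),
              sprintf("plant_%02d", seq_len(config$n_plant)),
              sprintf("animal_%02d", seq_len(config$n_animal)))
    kind <- rep(c("unicellular", "plant", "animal"),
                c(config$n_unicellular, config$n_plant, config$n_animal))
    n <- nrow(truth)
    m <- matrix(0L, nrow = n, ncol = length(taxa),
                dimnames = list(NULL, taxa))
    iu <- which(kind == "unicellular")
    ip <- which(kind == "plant")
    ia <- which(kind == "animal")
    for (g in seq_len(n)) {
      cc <- truth$conservation_class[g]
      if (cc == "core") {
        u <- rbinom(length(iu), 1L, 0.7)
        if (sum(u) == 0L) u[sample.int(length(iu), 1L)] <- 1L
        m[g, iu] <- u
        m[g, ip] <- rbinom(length(ip), 1L, 0.3)
        m[g, ia] <- rbinom(length(ia), 1L, 0.6)
      } else if (cc == "metazoan") {
        a <- rbinom(length(ia), 1L, 0.5)
        while (sum(a) < 2L) a[sample.int(length(ia), 1L)] <- 1L
        m[g, ia] <- a
      } else {
        if (runif(1) < 0.5) {
          # narrow: at most one animal, nothing else
          if (runif(1) < 0.5) m[g, sample(ia, 1L)] <- 1L
        } else {
          # plant-sharing without unicellular presence
          m[g, sample(ip, 1L)] <- 1L
          m[g, ia] <- rbinom(length(ia), 1L, 0.3)
        }
      }
    }
    list(profiles = bind_cols(tibble(gene_id = truth$gene_id), as_tibble(m)),
         taxon_kinds = tibble(taxon = taxa, kind = kind))
  })
}

#' Simulate expression data consistent with the true origin classes
#'
#' Produces decoupled maternal/zygotic component abundances and an
#' expression time course: maternal genes are high before the transition
#' and decay by `decay_fold` afterwards, strict-zygotic genes are absent
#' before and high after, maternal-zygotic genes are flat; multiplicative
#' log-normal noise (`noise_sd_log2`) is applied to the time course.
#'
#' @param truth truth table from [simulate_genome()].
#' @param config a [sim_config()].
#' @return tibble with `gene_id`, `maternal`, `zygotic`, and time-point
#'   columns `t1..tK`; attributes `timepoints` and `mzt_index`.
#' @export
simulate_expression <- function(truth, config = sim_config()) {
  with_seed_if(config$seed + 2L, {
    n <- nrow(truth)
    k <- config$timepoints
    level <- 2^(config$expr_meanlog2 + rnorm(n, 0, config$expr_sdlog2))
    pc <- config$presence_call
    maternal <- zygotic <- numeric(n)
    profile <- matrix(0, nrow = n, ncol = k)
    post <- (config$mzt_index + 1L):k
    pre <- seq_len(config$mzt_index)
    for (g in seq_len(n)) {
      oc <- as.character(truth$origin_class[g])
      L <- level[g]
      if (oc == "strict_maternal") {
        maternal[g] <- L
        profile[g, pre] <- L
        profile[g, post] <- L / config$decay_fold
      } else if (oc == "mostly_maternal") {
        zf <- runif(1, 0.05, 0.28)
        maternal[g] <- L * (1 - zf)
        zygotic[g] <- L * zf
        profile[g, pre] <- L
        profile[g, post] <- L / config$decay_fold
      } else if (oc == "maternal_zygotic") {
        maternal[g] <- L
        zygotic[g] <- runif(1, 0, L / 2)
        profile[g, ] <- L
      } else if (oc == "mostly_zygotic") {
        maternal[g] <- runif(1, 0.05, 0.9) * pc
        zygotic[g] <- L
        profile[g, pre] <- 0
        profile[g, post] <- L
      } else if (oc == "strict_zygotic") {
        zygotic[g] <- L
        profile[g, pre] <- runif(length(pre), 0, 0.5 * pc)
        profile[g, post] <- L
      } else {
        profile[g, ] <- runif(k, 0, 0.25 * pc)
      }
    }
    if (config$noise_sd_log2 > 0) {
      profile <- profile * 2^matrix(rnorm(n * k, 0, config$noise_sd_log2),
                                    nrow = n)
    }
    colnames(profile) <- sprintf("t%d", seq_len(k))
    out <- bind_cols(tibble(gene_id = truth$gene_id,
                            maternal = maternal, zygotic = zygotic),
                     as_tibble(profile))
    attr(out, "timepoints") <- colnames(profile)
    attr(out, "mzt_index") <- config$mzt_index
    out
  })
}

#' Simulate 1:1:1 ortholog tables with controlled rank preservation
#'
#' Given the anchor species' region-length table, constructs two partner
#' species whose 5' IGR ranks equal the anchor's perturbed by Gaussian
#' noise (`ortholog_rank_noise`). With zero noise the partner lengths are
#' an exact monotone transform of the anchor's (tie structure preserved),
#' so every log2 rank fold change is exactly zero. A planted maternal shift
#' (`maternal_rank_shift`) lowers the first partner's ranks for pairs
#' maternal in both species, reproducing a "maternal shifted right"
#' fold-change pattern in that pair only.
#'
#' @param metrics_a anchor-species table from [compute_region_table()].
#' @param truth_a anchor-species truth table.
#' @param config a [sim_config()].
#' @return list with `pairs_b`, `pairs_c` (tibbles `gene_a`, `gene_b`,
#'   `group_id`), `lengths_b`, `lengths_c` (tibbles `gene_id`, `igr5`),
#'   and `maternal_pairs_b`, `maternal_pairs_c` (anchor gene ids of pairs
#'   maternal in both species).
#' @export
simulate_orthologs <- function(metrics_a, truth_a, config = sim_config()) {
  with_seed_if(config$seed + 3L, {
    usable <- metrics_a[!is.na(metrics_a$igr5) & metrics_a$included_in_igr5_set, ,
                        drop = FALSE]
    n <- nrow(usable)
    if (n < 10L) abort("too few usable anchor genes for ortholog simulation")
    rank_a <- rank(usable$igr5, ties.method = "average") / n
    maternal_a <- usable$gene_id %in% truth_a$gene_id[truth_a$all_maternal]

    make_partner <- function(prefix, shift) {
      pid <- sprintf("%s_%s", prefix, usable$gene_id)
      maternal_both <- maternal_a & runif(n) < config$maternal_overlap
      if (config$ortholog_rank_noise == 0 && shift == 0) {
        # exact monotone transform of the anchor: ranks (incl. ties) preserved
        len <- 2L * usable$igr5
      } else {
        target <- rank_a + rnorm(n, 0, config$ortholog_rank_noise)
        target[maternal_both] <- target[maternal_both] - shift
        len <- sort(pmax(1L, as.integer(round(
          rlnorm(n, config$spacing_meanlog, config$spacing_sdlog)))))
        len <- len[rank(target, ties.method = "first")]
      }
      list(pid = pid, len = len, maternal_both = maternal_both)
    }
    pb <- make_partner("b", config$maternal_rank_shift)
    pc_ <- make_partner("c", 0)
    take <- sort(sample.int(n, max(2L, round(n * config$ortholog_fraction))))
    list(
      pairs_b = tibble(gene_a = usable$gene_id[take], gene_b = pb$pid[take],
                       group_id = sprintf("og%05d", take)),
      pairs_c = tibble(gene_a = usable$gene_id[take], gene_b = pc_$pid[take],
                       group_id = sprintf("og%05d", take)),
      lengths_b = tibble(gene_id = pb$pid, igr5 = pb$len),
      lengths_c = tibble(gene_id = pc_$pid, igr5 = pc_$len),
      maternal_pairs_b = usable$gene_id[take][pb$maternal_both[take]],
      maternal_pairs_c = usable$gene_id[take][pc_$maternal_both[take]]
    )
  })
}

#' Simulate an RNAi phenotype table for maternal genes
#'
#' Assigns each maternal gene an observed/none RNAi phenotype call. With
#' `rnai_effect > 0`, the no-phenotype genes are drawn preferentially from
#' genes with short 5' IGRs (weight `exp(-effect * igr5 rank)`), planting
#' the "functional maternal genes have longer 5' IGRs" pattern; with effect
#' 0 the assignment is a uniform null.
#'
#' @param metrics region-length table of the species.
#' @param truth truth table from [simulate_genome()].
#' @param config a [sim_config()].
#' @return tibble with columns `gene_id`, `phenotype`.
#' @export
simulate_rnai <- function(metrics, truth, config = sim_config()) {
  with_seed_if(config$seed + 4L, {
    maternal <- metrics[metrics$gene_id %in%
                          truth$gene_id[truth$all_maternal], , drop = FALSE]
    maternal <- maternal[!is.na(maternal$igr5), , drop = FALSE]
    n <- nrow(maternal)
    if (n < 4L) abort("too few maternal genes with usable 5' IGR")
    n_none <- max(1L, round(n * config$rnai_no_phenotype_fraction))
    r <- rank(maternal$igr5, ties.method = "average") / n
    w <- exp(-config$rnai_effect * r)
    none_idx <- sample.int(n, n_none, prob = w)
    phen <- rep("observed", n)
    phen[none_idx] <- "none"
    tibble(gene_id = maternal$gene_id, phenotype = phen)
  })
}
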