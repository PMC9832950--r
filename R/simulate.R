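#' Configuration of the pooled-F2 simulator
#'
#' The defaults emulate the study design the package targets: an
#' EMS-mutagenized diploid background (G:C-to-A:T-biased SNVs) segregating in
#' an F2 from a mutant x wild-type cross, one fully penetrant recessive causal
#' locus, two phenotype-selected pools of 37 plants, and per-sample short-read
#' depths matching the observed 22-58x (mutant parent 22x, wild-type parent
#' 57x, mutant pool 49x, wild-type pool 58x). The default genome is seven
#' 30-Mb chromosomes with the causal locus on the first: a genome-wide
#' median + 3 SD threshold needs chromosomes unlinked to the causal locus to
#' supply the near-zero ED background, exactly as in a real multi-chromosome
#' genome; a single-chromosome genome (every variant linked to the causal
#' locus) leaves the threshold unreachable by construction.
#'
#' @param seed RNG seed recorded in the ground truth.
#' @param chrom Character vector of chromosome ids; the causal locus lives on
#'   the first.
#' @param chrom_length_bp Lengths (bp) matching `chrom`.
#' @param n_background_variants Total EMS background SNVs carried by the
#'   mutant parent (default 2000), spread over chromosomes proportionally to
#'   length.
#' @param ems_transition_fraction Fraction of background SNVs that are
#'   G-to-A or C-to-T transitions (default 0.95).
#' @param causal_pos Position of the causal donor-site SNV on `chrom[1]`
#'   (default 17,200,000); the causal gene is laid out so this is the first
#'   base of its second intron.
#' @param n_f2 F2 individuals to simulate (default 400).
#' @param pool_size Individuals per phenotype-selected pool (default 37).
#' @param mean_depth Named per-role mean sequencing depths.
#' @param error_rate Per-read probability of reporting the other allele.
#' @param recomb_rate_cM_per_Mb Recombination rate (default 4).
#' @param n_genes Gene models tiled along the causal chromosome (default
#'   2200, the reported per-chromosome density scale).
#' @param causal If `FALSE`, no causal locus is planted and phenotypes are
#'   drawn independently of genotype (3:1).
#' @param all_reference If `TRUE` (implies no causal locus), every sample is
#'   reference at every site and alternate reads arise only from sequencing
#'   error — the null experiment for region calling.
#' @param with_genome Materialize the chromosome sequences (needed only when
#'   writing FASTA; use reduced lengths then).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom = sprintf("chrSim%d", 1:7),
                       chrom_length_bp = rep(30e6, 7),
                       n_background_variants = 2000L,
                       ems_transition_fraction = 0.95,
                       causal_pos = 17200000L,
                       n_f2 = 400L,
                       pool_size = 37L,
                       mean_depth = c(mutant_parent = 22, wildtype_parent = 57,
                                      mutant_pool = 49, wildtype_pool = 58),
                       error_rate = 0.002,
                       recomb_rate_cM_per_Mb = 4,
                       n_genes = 2200L,
                       causal = TRUE,
                       all_reference = FALSE,
                       with_genome = FALSE) {
  if (all_reference && causal) stop("all_reference requires causal = FALSE")
  stopifnot(length(chrom) == length(chrom_length_bp), length(chrom) >= 1,
            !anyDuplicated(chrom),
            causal_pos > 0, causal_pos <= chrom_length_bp[1],
            ems_transition_fraction >= 0, ems_transition_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            pool_size >= 1, n_f2 >= 2 * pool_size,
            setequal(names(mean_depth), sample_roles()))
  if (n_background_variants > sum(chrom_length_bp) / 100) {
    stop("variant density cap exceeded: n_background_variants > total length/100")
  }
  structure(list(seed = seed, chrom = chrom,
                 chrom_length_bp = chrom_length_bp,
                 n_background_variants = n_background_variants,
                 ems_transition_fraction = ems_transition_fraction,
                 causal_pos = causal_pos, n_f2 = n_f2, pool_size = pool_size,
                 mean_depth = mean_depth[sample_roles()],
                 error_rate = error_rate,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 n_genes = n_genes, causal = causal,
                 all_reference = all_reference,
                 with_genome = with_genome),
            class = "sim_config")
}

# Deterministic GT-free filler built from A/C-only codons: contains no G or T
# at all, hence no stop codons, no spurious splice donors.
.ac_filler <- function(n_nt) {
  codons <- c("AAC", "ACA", "CAA", "CAC", "CCA", "ACC", "CCC", "AAA")
  stopifnot(n_nt %% 3 == 0)
  paste(rep_len(codons, n_nt / 3), collapse = "")
}

#' Causal-gene fixture: five exons, donor-mutable second intron
#'
#' Constructs a synthetic plus-strand gene engineered to mirror the splicing
#' geometry the package models: a 1338-nt CDS over five exons (445 aa), a
#' second intron whose retention hits an in-frame stop after two intronic
#' codons (truncating the protein to 151 aa), and exactly one cryptic GT in
#' the second exon, 54 bp upstream of the exon 2/intron 2 junction, whose use
#' deletes 18 in-frame codons (427-aa product). The gene is laid out so the
#' first base of intron 2 (the mutable donor G) sits at `causal_pos`. The
#' local sequence is returned twice: reference (donor GT) and mutant (donor
#' AT, the EMS G-to-A transition), both carrying an `offsets` attribute so
#' they stand in for the full chromosome.
#'
#' @param chrom Chromosome id.
#' @param causal_pos Genomic position of the donor G of intron 2.
#' @param gene_id Identifier for the constructed gene.
#' @return List with `gene` ([gene_model()]), `genome_ref`, `genome_mut`,
#'   `causal_pos`, `intron_index` (2), `ref_allele` ("G"), `alt_allele` ("A").
#' @export
causal_gene_fixture <- function(chrom = "chrSim1", causal_pos = 17200000L,
                                gene_id = "causal_gene") {
  exon1 <- paste0("ATG", .ac_filler(147))                        # 150 nt
  exon2 <- paste0(.ac_filler(246), "GTC", .ac_filler(51))        # 300 nt, GT @ tail-54
  exon3 <- paste0("ATC", .ac_filler(297))                        # 300 nt
  exon4 <- .ac_filler(300)                                       # 300 nt
  exon5 <- paste0(.ac_filler(285), "TGA")                        # 288 nt
  i1 <- paste0("GT", .ac_filler(96), "AG")                       # 100 nt
  i2_ref <- paste0("GTC", "TAA", .ac_filler(111), "AG")          # 119 nt
  i3 <- paste0("GT", .ac_filler(96), "AG")
  i4 <- paste0("GT", .ac_filler(96), "AG")
  flank <- .ac_filler(501)

  parts_ref <- c(flank, exon1, i1, exon2, i2_ref, exon3, i3, exon4, i4,
                 exon5, flank)
  local_ref <- paste(parts_ref, collapse = "")
  # donor position of intron 2 within the local sequence (1-based)
  donor_local <- nchar(flank) + nchar(exon1) + nchar(i1) + nchar(exon2) + 1L
  stopifnot(substr(local_ref, donor_local, donor_local) == "G")
  local_mut <- local_ref
  substr(local_mut, donor_local, donor_local) <- "A"

  offset <- causal_pos - donor_local
  lens <- nchar(c(exon1, i1, exon2, i2_ref, exon3, i3, exon4, i4, exon5))
  bounds <- cumsum(c(nchar(flank), lens)) + offset
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  exon_rows <- c(1, 3, 5, 7, 9)
  exons <- data.frame(start = starts[exon_rows], end = ends[exon_rows])
  gene <- gene_model(gene_id = gene_id, chrom = chrom, strand = "+",
                     exons = exons, cds_start = exons$start[1],
                     cds_end = exons$end[5])
  mk_genome <- function(s) {
    g <- stats::setNames(s, chrom)
    attr(g, "offsets") <- stats::setNames(offset, chrom)
    g
  }
  list(gene = gene, genome_ref = mk_genome(local_ref),
       genome_mut = mk_genome(local_mut), causal_pos = causal_pos,
       intron_index = 2L, ref_allele = "G", alt_allele = "A")
}

# Tile simple two-exon background gene models along the causal chromosome,
# skipping the causal gene's neighborhood.
.background_genes <- function(config, avoid_start = NA, avoid_end = NA) {
  n <- config$n_genes
  if (n <= 0) return(list())
  spacing <- floor((config$chrom_length_bp[1] - 4000) / n)
  out <- vector("list", n)
  kept <- 0L
  for (j in seq_len(n)) {
    s <- (j - 1L) * spacing + 1000L
    e <- s + 1199L
    if (!is.na(avoid_start) && s <= avoid_end + 2000 && e >= avoid_start - 2000) next
    kept <- kept + 1L
    out[[kept]] <- gene_model(
      gene_id = sprintf("simg%05d", j), chrom = config$chrom[1],
      strand = if (j %% 2 == 0) "-" else "+",
      exons = data.frame(start = c(s, s + 600L), end = c(s + 399L, e)),
      cds_start = s, cds_end = e)
  }
  out[seq_len(kept)]
}

#' Simulate the parental genomes of the cross
#'
#' The mutant parent carries `n_background_variants` homozygous EMS-like SNVs
#' (a configurable fraction are G-to-A / C-to-T transitions) plus, when
#' `config$causal`, the causal donor-site SNV; the wild-type parent is the
#' reference. Positions are uniform without collision, spread over the
#' chromosomes proportionally to length.
#'
#' @param config A [sim_config()].
#' @return List with `variants` (chrom, pos, ref, alt, class, is_causal),
#'   `gene_models` (background genes + causal gene), `splice_fixture` (from
#'   [causal_gene_fixture()], NULL under the null), and `genome` (chromosome
#'   sequences if `with_genome`, else NULL).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fixture <- NULL
  avoid <- c(NA, NA)
  if (config$causal) {
    fixture <- causal_gene_fixture(config$chrom[1], config$causal_pos)
    avoid <- c(fixture$gene$gene_start, fixture$gene$gene_end)
  }
  genes <- .background_genes(config, avoid[1], avoid[2])
  if (config$causal) genes <- c(genes, list(fixture$gene))

  genome <- if (config$with_genome) .simulate_genome(config, fixture) else NULL

  n <- config$n_background_variants
  n_per <- as.vector(stats::rmultinom(1, n, prob = config$chrom_length_bp))
  chrom_v <- rep(config$chrom, n_per)
  pos <- integer(0)
  ref <- character(0)
  is_trans_all <- logical(0)
  for (ci in seq_along(config$chrom)) {
    ni <- n_per[ci]
    if (ni == 0) next
    is_trans <- stats::runif(ni) < config$ems_transition_fraction
    if (config$with_genome) {
      bases <- strsplit(genome[[config$chrom[ci]]], "")[[1]]
      gc_pos <- which(bases %in% c("G", "C"))
      if (ci == 1) gc_pos <- setdiff(gc_pos, config$causal_pos)
      p <- integer(ni)
      p[is_trans] <- sample(gc_pos, sum(is_trans))
      rest <- setdiff(seq_len(config$chrom_length_bp[ci]),
                      c(p[is_trans], if (ci == 1) config$causal_pos))
      p[!is_trans] <- sample(rest, sum(!is_trans))
      r <- bases[p]
    } else {
      p <- sample.int(config$chrom_length_bp[ci], ni + 1L)
      p <- setdiff(p, if (ci == 1) config$causal_pos else integer(0))[seq_len(ni)]
      r <- character(ni)
      r[is_trans] <- sample(c("G", "C"), sum(is_trans), replace = TRUE)
      r[!is_trans] <- sample(c("A", "C", "G", "T"), sum(!is_trans),
                             replace = TRUE)
    }
    pos <- c(pos, p)
    ref <- c(ref, r)
    is_trans_all <- c(is_trans_all, is_trans)
  }
  alt <- character(n)
  alt[ref == "G" & is_trans_all] <- "A"
  alt[ref == "C" & is_trans_all] <- "T"
  for (i in which(!is_trans_all | !(ref %in% c("G", "C")))) {
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
  }
  variants <- data.frame(chrom = chrom_v, pos = pos, ref = ref, alt = alt,
                         class = "SNP", is_causal = FALSE,
                         stringsAsFactors = FALSE)
  if (config$causal) {
    variants <- rbind(variants,
                      data.frame(chrom = config$chrom[1],
                                 pos = config$causal_pos,
                                 ref = fixture$ref_allele,
                                 alt = fixture$alt_allele, class = "SNP",
                                 is_causal = TRUE, stringsAsFactors = FALSE))
  }
  variants <- variants[order(match(variants$chrom, config$chrom),
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, gene_models = genes, splice_fixture = fixture,
       genome = genome)
}

# Random chromosome sequences with the causal gene's local sequence embedded
# on the first chromosome.
.simulate_genome <- function(config, fixture) {
  codes <- c(65L, 67L, 71L, 84L) # A C G T
  seqs <- vapply(config$chrom_length_bp, function(L) {
    intToUtf8(codes[sample.int(4L, L, replace = TRUE)])
  }, "")
  names(seqs) <- config$chrom
  if (!is.null(fixture)) {
    off <- attr(fixture$genome_ref, "offsets")[[config$chrom[1]]]
    local <- fixture$genome_ref[[config$chrom[1]]]
    s <- seqs[[config$chrom[1]]]
    substr(s, off + 1L, off + nchar(local)) <- local
    seqs[[config$chrom[1]]] <- s
  }
  seqs
}

#' Simulate the F2 generation
#'
#' Every F2 individual is formed from two F1 gametes. Crossovers per gamete
#' and chromosome are Poisson with mean equal to that chromosome's genetic
#' length (Haldane, no interference); breakpoints are uniform on the genetic
#' map; chromosomes assort independently.
#'
#' @param parents Output of [simulate_parents()].
#' @param config The [sim_config()].
#' @return List with `genotypes` (n_f2 x n_variants matrix of mutant-allele
#'   dosages 0/1/2) and `phenotype` ("mutant"/"wildtype"); under the full
#'   model phenotype is mutant iff the causal dosage is 2.
#' @export
simulate_f2 <- function(parents, config) {
  n_var <- nrow(parents$variants)
  rate <- config$recomb_rate_cM_per_Mb
  geno <- matrix(0L, nrow = config$n_f2, ncol = n_var)
  for (ci in seq_along(config$chrom)) {
    idx <- which(parents$variants$chrom == config$chrom[ci])
    if (length(idx) == 0) next
    morgans <- config$chrom_length_bp[ci] / 1e6 * rate / 100
    v_m <- parents$variants$pos[idx] / 1e6 * rate / 100
    gamete <- function() {
      k <- stats::rpois(1, morgans)
      phase <- sample.int(2L, 1L) - 1L
      if (k == 0) return(rep.int(phase, length(idx)))
      bp <- sort(stats::runif(k, 0, morgans))
      (phase + findInterval(v_m, bp)) %% 2L
    }
    for (i in seq_len(config$n_f2)) geno[i, idx] <- gamete() + gamete()
  }
  causal_idx <- which(parents$variants$is_causal)
  phenotype <- if (length(causal_idx) == 1) {
    ifelse(geno[, causal_idx] == 2L, "mutant", "wildtype")
  } else {
    sample(c("mutant", "wildtype"), config$n_f2, replace = TRUE,
           prob = c(0.25, 0.75))
  }
  list(genotypes = geno, phenotype = phenotype)
}

#' Simulate pooled sequencing of the four samples
#'
#' Pools are the first `pool_size` individuals of each phenotype class. For
#' every variant and sample, depth is Poisson around the per-role mean and
#' alternate-read counts are binomial at the pool allele frequency, perturbed
#' toward the other allele by the symmetric error rate. Parents use their
#' homozygous frequencies (mutant parent 1, wild-type parent 0).
#'
#' @param f2 Output of [simulate_f2()].
#' @param parents Output of [simulate_parents()].
#' @param config The [sim_config()].
#' @return Variant table with the eight per-role count columns plus
#'   `is_causal`, ready for [ed_profile()].
#' @export
simulate_pools <- function(f2, parents, config) {
  mut_idx <- which(f2$phenotype == "mutant")
  wt_idx <- which(f2$phenotype == "wildtype")
  if (length(mut_idx) < config$pool_size || length(wt_idx) < config$pool_size) {
    stop("not enough individuals of each phenotype for pools of ",
         config$pool_size)
  }
  mut_idx <- mut_idx[seq_len(config$pool_size)]
  wt_idx <- wt_idx[seq_len(config$pool_size)]
  n_var <- nrow(parents$variants)
  freq <- list(
    mutant_parent = rep.int(if (config$all_reference) 0 else 1, n_var),
    wildtype_parent = rep.int(0, n_var),
    mutant_pool = colSums(f2$genotypes[mut_idx, , drop = FALSE]) /
      (2 * config$pool_size),
    wildtype_pool = colSums(f2$genotypes[wt_idx, , drop = FALSE]) /
      (2 * config$pool_size)
  )
  if (config$all_reference) freq <- lapply(freq, function(x) x * 0)
  out <- parents$variants
  e <- config$error_rate
  for (role in sample_roles()) {
    depth <- stats::rpois(n_var, config$mean_depth[[role]])
    f_eff <- freq[[role]] * (1 - e) + (1 - freq[[role]]) * e
    alt <- stats::rbinom(n_var, depth, f_eff)
    out[[paste0(role, "_ref")]] <- depth - alt
    out[[paste0(role, "_alt")]] <- alt
  }
  out
}

#' Run the full simulator and optionally write its files
#'
#' Seeds the RNG once from `config$seed`, chains
#' [simulate_parents()] -> [simulate_f2()] -> [simulate_pools()], and, when
#' `dir` is given, writes `pools.vcf`, `genes.gff3`, `truth.tsv` and (with
#' `with_genome`) `genome.fa`. Fixed seed implies byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `config`, `variants` (counts table), `gene_models`,
#'   `f2`, `splice_fixture`, `genome`, and `truth` (causal position/gene,
#'   phenotype counts, seed).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  set.seed(config$seed)
  parents <- simulate_parents(config)
  f2 <- simulate_f2(parents, config)
  variants <- simulate_pools(f2, parents, config)
  truth <- list(seed = config$seed,
                causal_chrom = if (config$causal) config$chrom[1] else NA,
                causal_pos = if (config$causal) config$causal_pos else NA,
                causal_gene_id = if (config$causal)
                  parents$splice_fixture$gene$gene_id else NA,
                n_mutant = sum(f2$phenotype == "mutant"),
                n_wildtype = sum(f2$phenotype == "wildtype"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_vcf(variants, file.path(dir, "pools.vcf"))
    write_gff3(parents$gene_models, file.path(dir, "genes.gff3"))
    tr <- variants[, c("chrom", "pos", "ref", "alt", "is_causal")]
    utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (config$with_genome) {
      write_fasta(parents$genome, file.path(dir, "genome.fa"))
    }
  }
  list(config = config, variants = variants, gene_models = parents$gene_models,
       f2 = f2, splice_fixture = parents$splice_fixture,
       genome = parents$genome, truth = truth)
}
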