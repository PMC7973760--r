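#' Parameterization of the synthetic ddRAD world
#'
#' One object fully determines the synthetic genome, read sets and genotype
#' matrices (given its seed). Defaults emulate the structure of a real
#' multiplexed peach ddRAD run at desk scale: 8 pools of 24 samples, a
#' per-sample read-pair yield with 28.14% coefficient of variation, 225-b
#' post-trim reads, a 300-400 bp size-selection window with a pool-level
#' window shift for the second batch of pools (the hypothesized
#' manual-vs-automatic size-selection batch effect, made concrete),
#' centromere-like spans with no restriction sites, and one high-homology
#' hotspot region whose reads collapse onto a single location
#' (a multi-mapping proxy for an organellar insert). The default genome is
#' 1 Mb with locus and variant counts scaled per Mb so that per-locus depth
#' (~16 read pairs per locus) matches the real platform.
#'
#' @param genome_length Total genome size in bp (default 1e6).
#' @param n_chrom Chromosomes of equal length (default 2).
#' @param gc GC content of background sequence (default 0.38, peach-like).
#' @param enzymes Length-2 character vector of built-in enzyme names
#'   (default PstI/MboI).
#' @param n_loci_per_mb AB/BA locus cassettes planted per Mb (default 280,
#'   the per-Mb density implied by 63,730 loci on a 230-Mb genome).
#' @param rare_sites_per_kb,frequent_sites_per_kb Background single-site
#'   densities for the rare/frequent cutter (defaults 0.05 and 0.5; kept low
#'   because cassettes already carry most sites).
#' @param locus_length_spread Half-width (bp) by which planted locus lengths
#'   extend beyond the window on each side (default 100), so window shifts
#'   change the captured locus set.
#' @param centromere_fraction Central fraction of each chromosome kept free
#'   of planted sites (default 0.15).
#' @param hotspot_copies Tandem copies of the hotspot unit (default 10;
#'   0 disables the hotspot).
#' @param hotspot_unit_bp Hotspot unit length (default 1000).
#' @param n_ssr_tracts Microsatellite tracts planted (default 30).
#' @param n_pools,samples_per_pool Multiplexing layout (default 8 x 24).
#' @param window_min,window_max Size-selection window (default 300-400).
#' @param pool_window_shift Bp added to both window bounds for
#'   `shifted_pools` (default 20; 0 means exchangeable samples).
#' @param shifted_pools Indices of pools receiving the shift (default pools
#'   6..n_pools, mirroring the observed two-batch block structure).
#' @param yield_mean_pairs,yield_cv Per-sample read-pair yield mean and CV
#'   (defaults 4500 and 0.2814).
#' @param read_length Aligned read length in bp (default 225, post-trim).
#' @param n_snp,n_indel,n_ssr_variants Variant counts per type for the
#'   genotype generator (defaults 800/100/30 per default genome).
#' @param snp_transition_prob Probability that a synthetic SNP is a
#'   transition (default 0.571, which yields a transition/transversion
#'   ratio of about 1.33, the value typical of peach ddRAD SNP sets).
#' @param maf_shape1,maf_shape2 Beta parameters; per-variant MAF is
#'   `0.5 * rbeta(shape1, shape2)` (defaults 0.8/2.5: many rare, some
#'   common alleles).
#' @param maf_fixed Optional fixed MAF overriding the Beta draw.
#' @param missing_rate Per-genotype missing probability (default 0.0133).
#' @param coverage_linked_missingness When TRUE, per-sample missing rates
#'   are scaled inversely to realized yields (low-yield samples miss more).
#' @param seed Integer master seed; all generator randomness flows from it
#'   via fixed per-stage offsets (genome +0, reads +1, genotypes +2).
#' @return Object of class `synthetic_design`.
#' @export
synthetic_design <- function(genome_length = 1e6, n_chrom = 2L, gc = 0.38,
                             enzymes = c("PstI", "MboI"),
                             n_loci_per_mb = 280,
                             rare_sites_per_kb = 0.05,
                             frequent_sites_per_kb = 0.5,
                             locus_length_spread = 100L,
                             centromere_fraction = 0.15,
                             hotspot_copies = 10L, hotspot_unit_bp = 1000L,
                             n_ssr_tracts = 30L,
                             n_pools = 8L, samples_per_pool = 24L,
                             window_min = 300L, window_max = 400L,
                             pool_window_shift = 20L, shifted_pools = NULL,
                             yield_mean_pairs = 4500, yield_cv = 0.2814,
                             read_length = 225L,
                             n_snp = 800L, n_indel = 100L,
                             n_ssr_variants = 30L,
                             snp_transition_prob = 0.571,
                             maf_shape1 = 0.8, maf_shape2 = 2.5,
                             maf_fixed = NULL,
                             missing_rate = 0.0133,
                             coverage_linked_missingness = FALSE,
                             seed = 1L) {
  stopifnot(genome_length >= 1e4, n_chrom >= 1L, gc > 0, gc < 1,
            length(enzymes) == 2L, n_loci_per_mb >= 0,
            rare_sites_per_kb >= 0, frequent_sites_per_kb >= 0,
            centromere_fraction >= 0, centromere_fraction < 0.8,
            n_pools >= 1L, samples_per_pool >= 1L,
            window_min <= window_max, yield_mean_pairs > 0, yield_cv >= 0,
            read_length >= 1L, missing_rate >= 0, missing_rate < 1)
  if (is.null(shifted_pools)) {
    shifted_pools <- if (n_pools >= 6L) seq(6L, n_pools)
                     else seq_len(n_pools)[-seq_len(ceiling(n_pools / 2))]
  }
  seed <- as.integer(seed)
  stopifnot(!is.na(seed), abs(seed) < 2^31 - 10)
  structure(
    list(genome_length = genome_length, n_chrom = as.integer(n_chrom),
         gc = gc, enzymes = enzymes, n_loci_per_mb = n_loci_per_mb,
         rare_sites_per_kb = rare_sites_per_kb,
         frequent_sites_per_kb = frequent_sites_per_kb,
         locus_length_spread = as.integer(locus_length_spread),
         centromere_fraction = centromere_fraction,
         hotspot_copies = as.integer(hotspot_copies),
         hotspot_unit_bp = as.integer(hotspot_unit_bp),
         n_ssr_tracts = as.integer(n_ssr_tracts),
         n_pools = as.integer(n_pools),
         samples_per_pool = as.integer(samples_per_pool),
         window_min = as.integer(window_min),
         window_max = as.integer(window_max),
         pool_window_shift = as.integer(pool_window_shift),
         shifted_pools = as.integer(shifted_pools),
         yield_mean_pairs = yield_mean_pairs, yield_cv = yield_cv,
         read_length = as.integer(read_length),
         n_snp = as.integer(n_snp), n_indel = as.integer(n_indel),
         n_ssr_variants = as.integer(n_ssr_variants),
         snp_transition_prob = snp_transition_prob,
         maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
         maf_fixed = maf_fixed, missing_rate = missing_rate,
         coverage_linked_missingness = isTRUE(coverage_linked_missingness),
         seed = seed),
    class = "synthetic_design"
  )
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_design> %.2g Mb genome, %d chrom; %s; window [%d, %d]",
    " (+%d bp for pools %s)\n  %d pools x %d samples,",
    " yield %.3g pairs (CV %.1f%%), seed %d\n"),
    x$genome_length / 1e6, x$n_chrom, paste(x$enzymes, collapse = "/"),
    x$window_min, x$window_max, x$pool_window_shift,
    paste(x$shifted_pools, collapse = ","), x$n_pools, x$samples_per_pool,
    x$yield_mean_pairs, 100 * x$yield_cv, x$seed))
  invisible(x)
}

# --- genome generation -------------------------------------------------------

# Replace every occurrence of the given motifs in chars with a mutated base,
# except inside protected intervals (start,end 1-based on this chromosome).
# Iterates because a mutation can create a new site. Vectorized over hits:
# one pass mutates the midmost unprotected base of every match.
.scrub_sites <- function(chars, motifs, protected = NULL, max_iter = 25L) {
  prot <- logical(length(chars))
  if (!is.null(protected) && nrow(protected)) {
    for (i in seq_len(nrow(protected))) {
      prot[protected$start[i]:protected$end[i]] <- TRUE
    }
  }
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    seq_str <- paste(chars, collapse = "")
    subject <- Biostrings::DNAString(seq_str)
    for (motif in motifs) {
      hits <- BiocGenerics::start(
        Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                 fixed = "subject"))
      if (!length(hits)) next
      k <- nchar(motif)
      for (s in hits) {
        span <- s:(s + k - 1L)
        free <- span[!prot[span]]
        if (!length(free)) next
        p <- free[(length(free) + 1L) %/% 2L]
        chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  paste(chars, collapse = "")
}

# Draw n non-overlapping intervals of the given widths inside [1, L],
# avoiding `avoid` intervals (data.table start,end) and keeping `gap` bp
# between placements. Returns data.table(start, end) or errors.
.place_intervals <- function(n, widths, L, avoid, gap = 50L,
                             max_tries = 50L) {
  placed <- data.table::data.table(start = integer(0), end = integer(0))
  occupied <- data.table::copy(avoid)
  for (i in seq_len(n)) {
    w <- widths[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - w - 2L * gap, 1L) + gap
      e <- s + w - 1L
      clash <- nrow(occupied) &&
        any(s - gap <= occupied$end & e + gap >= occupied$start)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not place synthetic feature ", i,
           ": genome too crowded (overlapping planted features)",
           call. = FALSE)
    }
    placed <- rbind(placed, data.table::data.table(start = s, end = e))
    occupied <- rbind(occupied,
                      data.table::data.table(start = s, end = e))
  }
  placed
}

.random_chars <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome with planted restriction landscape
#'
#' Builds a seeded random genome whose restriction-site landscape is known
#' exactly: background sequence is scrubbed of all accidental recognition
#' sites of the design's enzymes, then AB/BA locus cassettes (rare-cutter
#' site, spacer, frequent-cutter site, random orientation, spacer lengths
#' spanning the size window plus `locus_length_spread` on each side),
#' background single sites, microsatellite tracts and a tandem-repeated
#' hotspot insert are planted at non-overlapping positions outside the
#' centromere-like spans. Truth tables for every planted feature are
#' returned; planted cut sites are verified against [find_cut_sites()]
#' before returning.
#'
#' @param design A [synthetic_design()].
#' @return Object of class `synthetic_genome`: `genome` (DNAStringSet),
#'   `sites` (enzyme/chrom/motif_start/cut, 0-based), `loci`
#'   (chrom/start/end/length/left_end/right_end/in_hotspot, 0-based
#'   half-open fragment coordinates between cuts), `ssr_tracts`
#'   (chrom/start/end/motif/repeats, 1-based), `centromeres`, `hotspot`
#'   (span + unit length), `design`.
#' @export
gen_genome <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  withr::with_seed(design$seed, .gen_genome_impl(design))
}

.gen_genome_impl <- function(design) {
  enz <- lapply(design$enzymes, .as_enzyme)
  motifs <- vapply(enz, `[[`, "", "recognition")
  chrom_len <- as.integer(round(design$genome_length / design$n_chrom))
  chrom_names <- sprintf("chr%02d", seq_len(design$n_chrom))
  mb <- design$genome_length / 1e6
  n_loci_total <- round(mb * design$n_loci_per_mb)
  n_rare <- round(design$rare_sites_per_kb * design$genome_length / 1000)
  n_freq <- round(design$frequent_sites_per_kb * design$genome_length / 1000)

  seqs <- list(); sites <- list(); loci <- list(); ssrs <- list()
  centromeres <- list(); hotspot <- NULL

  # per-chromosome feature budget (round-robin split)
  split_count <- function(total) {
    base <- total %/% design$n_chrom
    extra <- total - base * design$n_chrom
    base + (seq_len(design$n_chrom) <= extra)
  }
  loci_per_chrom <- split_count(n_loci_total)
  rare_per_chrom <- split_count(n_rare)
  freq_per_chrom <- split_count(n_freq)
  ssr_per_chrom <- split_count(design$n_ssr_tracts)

  ssr_motif_pool <- c("T", "A", "AT", "AG", "CT", "AC", "GT", "ATG", "AAG",
                      "AAT", "AGAT", "AAAT", "AACCT", "AGGTTT")
  ssr_motif_prob <- c(10, 8, 24, 23, 16, 3, 3, 4, 3, 3, 2, 2, 1, 1)
  thr <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)

  for (k in seq_len(design$n_chrom)) {
    chrom <- chrom_names[k]
    chars <- .random_chars(chrom_len, design$gc)
    cen_w <- as.integer(round(design$centromere_fraction * chrom_len))
    cen_s <- as.integer((chrom_len - cen_w) %/% 2) + 1L
    cen <- data.table::data.table(start = cen_s, end = cen_s + cen_w - 1L)
    centromeres[[k]] <- data.table::data.table(
      chrom = chrom, start = cen_s - 1L, end = cen_s + cen_w - 1L)
    avoid <- data.table::copy(cen)

    # hotspot: tandem copies of one unit on the first chromosome
    hot_rows <- NULL
    if (k == 1L && design$hotspot_copies > 0L) {
      unit_len <- design$hotspot_unit_bp
      hot_len <- unit_len * design$hotspot_copies
      hs <- as.integer(round(chrom_len * 0.75))
      if (hs + hot_len + 1000L > chrom_len) {
        stop("overlapping planted features: hotspot does not fit",
             call. = FALSE)
      }
      if (hs <= cen$end && hs + hot_len - 1L >= cen$start) {
        stop("overlapping planted features: hotspot hits centromere",
             call. = FALSE)
      }
      hotspot <- list(chrom = chrom, start = hs - 1L,
                      end = hs - 1L + hot_len, unit_bp = unit_len,
                      copies = design$hotspot_copies)
      avoid <- rbind(avoid,
                     data.table::data.table(start = hs,
                                            end = hs + hot_len - 1L))
      hot_rows <- list(hs = hs, unit_len = unit_len)
    }

    # locus cassettes: enzA-motif .. spacer .. enzB-motif (random order)
    nl <- loci_per_chrom[k]
    spread <- design$locus_length_spread
    frag_lens <- if (nl > 0L) sample(
      seq(design$window_min - spread, design$window_max + spread), nl,
      replace = TRUE) else integer(0)
    # fragment length is cut-to-cut; cassette width depends on orientation
    orient <- sample(c(TRUE, FALSE), nl, replace = TRUE)   # TRUE: A first
    widths <- integer(nl)
    for (i in seq_len(nl)) {
      a <- enz[[if (orient[i]) 1L else 2L]]
      b <- enz[[if (orient[i]) 2L else 1L]]
      # left cut at la_start0 + a_off, right cut at lb_start0 + b_off;
      # cassette spans both motifs entirely
      widths[i] <- a$cut_offset + frag_lens[i] +
        (nchar(b$recognition) - b$cut_offset)
    }
    cass <- if (nl > 0L) .place_intervals(nl, widths, chrom_len, avoid)
            else data.table::data.table(start = integer(0), end = integer(0))
    if (nl > 0L) avoid <- rbind(avoid, cass)
    protected <- data.table::data.table(start = integer(0), end = integer(0))
    for (i in seq_len(nl)) {
      a <- enz[[if (orient[i]) 1L else 2L]]
      b <- enz[[if (orient[i]) 2L else 1L]]
      s0 <- cass$start[i]                       # 1-based motif A start
      b_start <- s0 + a$cut_offset + frag_lens[i] - b$cut_offset
      for (mo in list(list(e = a, at = s0), list(e = b, at = b_start))) {
        m <- mo$e$recognition
        chars[mo$at:(mo$at + nchar(m) - 1L)] <-
          strsplit(m, "", fixed = TRUE)[[1L]]
        sites[[length(sites) + 1L]] <- data.table::data.table(
          enzyme = mo$e$name, chrom = chrom, motif_start = mo$at - 1L,
          cut = mo$at - 1L + mo$e$cut_offset)
        protected <- rbind(protected, data.table::data.table(
          start = mo$at, end = mo$at + nchar(m) - 1L))
      }
      cut_left <- s0 - 1L + a$cut_offset
      loci[[length(loci) + 1L]] <- data.table::data.table(
        chrom = chrom, start = cut_left, end = cut_left + frag_lens[i],
        length = frag_lens[i], left_end = a$name, right_end = b$name,
        in_hotspot = FALSE)
    }

    # background single sites
    for (bg in list(list(e = enz[[1L]], n = rare_per_chrom[k]),
                    list(e = enz[[2L]], n = freq_per_chrom[k]))) {
      if (bg$n == 0L) next
      m <- bg$e$recognition
      pl <- .place_intervals(bg$n, rep(nchar(m), bg$n), chrom_len, avoid)
      avoid <- rbind(avoid, pl)
      for (i in seq_len(nrow(pl))) {
        chars[pl$start[i]:(pl$start[i] + nchar(m) - 1L)] <-
          strsplit(m, "", fixed = TRUE)[[1L]]
        sites[[length(sites) + 1L]] <- data.table::data.table(
          enzyme = bg$e$name, chrom = chrom, motif_start = pl$start[i] - 1L,
          cut = pl$start[i] - 1L + bg$e$cut_offset)
      }
      protected <- rbind(protected, pl)
    }

    # microsatellite tracts (above threshold, perfect)
    ns <- ssr_per_chrom[k]
    if (ns > 0L) {
      mi <- sample(length(ssr_motif_pool), ns, replace = TRUE,
                   prob = ssr_motif_prob)
      reps <- thr[as.character(nchar(ssr_motif_pool[mi]))] +
        stats::rpois(ns, 3)
      widths <- nchar(ssr_motif_pool[mi]) * reps
      pl <- .place_intervals(ns, widths, chrom_len, avoid)
      avoid <- rbind(avoid, pl)
      for (i in seq_len(ns)) {
        tract <- strrep(ssr_motif_pool[mi[i]], reps[i])
        chars[pl$start[i]:(pl$start[i] + widths[i] - 1L)] <-
          strsplit(tract, "", fixed = TRUE)[[1L]]
        ssrs[[length(ssrs) + 1L]] <- data.table::data.table(
          chrom = chrom, start = pl$start[i], end = pl$end[i],
          motif = ssr_motif_pool[mi[i]], repeats = reps[i])
      }
      protected <- rbind(protected, pl)
    }

    # write the hotspot unit (carries one cassette) and tile it
    if (!is.null(hot_rows)) {
      unit_len <- hot_rows$unit_len
      unit <- .random_chars(unit_len, design$gc)
      unit <- strsplit(.scrub_sites(unit, motifs), "", fixed = TRUE)[[1L]]
      a <- enz[[1L]]; b <- enz[[2L]]
      fl <- as.integer(round((design$window_min + design$window_max) / 2))
      a_at <- 101L
      b_at <- a_at + a$cut_offset + fl - b$cut_offset
      stopifnot(b_at + nchar(b$recognition) - 1L <= unit_len)
      unit[a_at:(a_at + nchar(a$recognition) - 1L)] <-
        strsplit(a$recognition, "", fixed = TRUE)[[1L]]
      unit[b_at:(b_at + nchar(b$recognition) - 1L)] <-
        strsplit(b$recognition, "", fixed = TRUE)[[1L]]
      for (cp in seq_len(design$hotspot_copies)) {
        off <- hot_rows$hs + (cp - 1L) * unit_len     # 1-based copy start
        chars[off:(off + unit_len - 1L)] <- unit
        for (mo in list(list(e = a, at = off + a_at - 1L),
                        list(e = b, at = off + b_at - 1L))) {
          sites[[length(sites) + 1L]] <- data.table::data.table(
            enzyme = mo$e$name, chrom = chrom, motif_start = mo$at - 1L,
            cut = mo$at - 1L + mo$e$cut_offset)
          protected <- rbind(protected, data.table::data.table(
            start = mo$at, end = mo$at + nchar(mo$e$recognition) - 1L))
        }
        cut_left <- (hot_rows$hs + (cp - 1L) * unit_len - 1L) + a_at - 1L +
          a$cut_offset
        loci[[length(loci) + 1L]] <- data.table::data.table(
          chrom = chrom, start = cut_left, end = cut_left + fl,
          length = fl, left_end = a$name, right_end = b$name,
          in_hotspot = TRUE)
      }
    }

    # final scrub outside planted motifs (junction artifacts)
    seqs[[chrom]] <- .scrub_sites(chars, motifs, protected = protected)
  }

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chrom_names
  sites_dt <- if (length(sites)) data.table::rbindlist(sites) else
    data.table::data.table(enzyme = character(0), chrom = character(0),
                           motif_start = integer(0), cut = integer(0))
  data.table::setorderv(sites_dt, c("chrom", "motif_start"))
  # verify truth: every planted site found, nothing extra
  for (e in enz) {
    for (ch in chrom_names) {
      found <- find_cut_sites(genome[[which(chrom_names == ch)]], e)
      planted <- sort(sites_dt[sites_dt$enzyme == e$name &
                               sites_dt$chrom == ch, ]$cut)
      if (!identical(found, unique(planted))) {
        stop("synthetic genome verification failed for ", e$name, " on ",
             ch, " (", length(found), " found vs ",
             length(unique(planted)), " planted)", call. = FALSE)
      }
    }
  }
  loci_dt <- if (length(loci)) data.table::rbindlist(loci) else
    data.table::data.table(chrom = character(0), start = integer(0),
                           end = integer(0), length = integer(0),
                           left_end = character(0), right_end = character(0),
                           in_hotspot = logical(0))
  structure(
    list(genome = genome, sites = sites_dt, loci = loci_dt,
         ssr_tracts = if (length(ssrs)) data.table::rbindlist(ssrs) else
           data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), motif = character(0),
                                  repeats = integer(0)),
         centromeres = data.table::rbindlist(centromeres),
         hotspot = hotspot, design = design),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d seq / %.3g Mb; %d planted sites, %d loci, %d SSR tracts%s\n",
    length(x$genome), sum(Biostrings::width(x$genome)) / 1e6,
    nrow(x$sites), nrow(x$loci), nrow(x$ssr_tracts),
    if (!is.null(x$hotspot)) sprintf("; hotspot %s:%d-%d (%dx)",
                                     x$hotspot$chrom, x$hotspot$start,
                                     x$hotspot$end, x$hotspot$copies) else ""))
  invisible(x)
}

# --- read generation ---------------------------------------------------------

#' Generate per-sample aligned read sets
#'
#' Digests the synthetic genome with the design's enzyme pair, then for each
#' sample draws a read-pair yield from a gamma distribution with the design's
#' mean and CV, and samples AB/BA fragments whose length falls inside that
#' sample's pool-shifted size window (uniformly, with replacement; hotspot
#' fragments get `copies`-fold weight collapsed onto the first copy's
#' coordinates as a multi-mapping proxy). Each sampled fragment emits one
#' read pair: two aligned segments of `read_length` bp at the fragment ends
#' (whole fragment when shorter). Fully deterministic given the design seed.
#'
#' @param sg A `synthetic_genome` from [gen_genome()] (the design is taken
#'   from it) or a [synthetic_design()] (genome generated on the fly).
#' @param seed Optional integer overriding the read-stage seed (default
#'   `design$seed + 1`); lets replicate studies redraw reads over one fixed
#'   genome.
#' @return List of class `synthetic_reads`: `alignments`
#'   (an [alignment_set()]), `pool_map` (named vector), `yields`
#'   (`data.table` sample/pool/pairs), `windows` (per-pool bounds),
#'   `digest` (the `digest_result`).
#' @export
gen_reads <- function(sg, seed = NULL) {
  if (inherits(sg, "synthetic_design")) sg <- gen_genome(sg)
  stopifnot(inherits(sg, "synthetic_genome"))
  design <- sg$design
  if (is.null(seed)) seed <- design$seed + 1L
  withr::with_seed(as.integer(seed), .gen_reads_impl(sg, design))
}

.gen_reads_impl <- function(sg, design) {
  dg <- digest(sg$genome, as.list(design$enzymes))
  fr <- dg$fragments
  cls <- .classify_fragments(fr, design$enzymes[1L], design$enzymes[2L])
  ab <- fr[cls == "AB+BA"]
  if (!nrow(ab)) stop("no AB+BA fragments in the synthetic digest",
                      call. = FALSE)
  # hotspot weighting + coordinate collapse onto the first copy
  weight <- rep(1, nrow(ab))
  collapse_off <- rep(0L, nrow(ab))
  if (!is.null(sg$hotspot)) {
    hs <- sg$hotspot
    in_hot <- ab$chrom == hs$chrom & ab$start >= hs$start & ab$end <= hs$end
    copy_idx <- integer(nrow(ab))
    copy_idx[in_hot] <- (ab$start[in_hot] - hs$start) %/% hs$unit_bp
    collapse_off[in_hot] <- copy_idx[in_hot] * hs$unit_bp
    # drop non-first copies; first copy carries the full weight
    first_hot <- in_hot & copy_idx == 0L
    weight[first_hot] <- weight[first_hot] +
      vapply(which(first_hot), function(i) {
        sum(in_hot & ab$start - collapse_off == ab$start[i] &
              ab$chrom == ab$chrom[i]) - 1L
      }, 0)
    keep <- !in_hot | first_hot
    ab <- ab[keep]; weight <- weight[keep]
  }
  n_samples <- design$n_pools * design$samples_per_pool
  samples <- sprintf("S%03d", seq_len(n_samples))
  pool_map <- stats::setNames(
    rep(sprintf("pool_%d", seq_len(design$n_pools)),
        each = design$samples_per_pool), samples)
  shifts <- ifelse(seq_len(design$n_pools) %in% design$shifted_pools,
                   design$pool_window_shift, 0L)
  windows <- data.table::data.table(
    pool = sprintf("pool_%d", seq_len(design$n_pools)),
    min_bp = design$window_min + shifts,
    max_bp = design$window_max + shifts)
  yields <- if (design$yield_cv > 0) {
    shape <- 1 / design$yield_cv^2
    pmax(1L, as.integer(round(stats::rgamma(
      n_samples, shape = shape, rate = shape / design$yield_mean_pairs))))
  } else rep(as.integer(round(design$yield_mean_pairs)), n_samples)
  rl <- design$read_length
  segs <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    w <- windows[windows$pool == pool_map[[samples[i]]], ]
    cand <- which(ab$length >= w$min_bp & ab$length <= w$max_bp)
    if (!length(cand)) {
      stop("empty windowed fragment set for ", pool_map[[samples[i]]],
           call. = FALSE)
    }
    pick <- cand[sample.int(length(cand), yields[i], replace = TRUE,
                            prob = weight[cand])]
    st <- ab$start[pick]; en <- ab$end[pick]
    segs[[i]] <- data.table::data.table(
      sample = samples[i],
      chrom = rep(ab$chrom[pick], 2L),
      start = c(st, pmax(st, en - rl)),
      end = c(pmin(en, st + rl), en),
      mapq = 60L)
  }
  seqlens <- dg$seqlengths
  aln <- alignment_set(data.table::rbindlist(segs), seqlens, mapq_gt = 3L)
  structure(
    list(alignments = aln, pool_map = pool_map,
         yields = data.table::data.table(sample = samples,
                                         pool = unname(pool_map[samples]),
                                         pairs = yields),
         windows = windows, digest = dg),
    class = "synthetic_reads"
  )
}

#' @export
print.synthetic_reads <- function(x, ...) {
  cat(sprintf(
    "<synthetic_reads> %d samples in %d pools; %.3g read pairs (realized CV %.1f%%)\n",
    nrow(x$yields), length(unique(x$yields$pool)), sum(x$yields$pairs),
    100 * stats::sd(x$yields$pairs) / mean(x$yields$pairs)))
  invisible(x)
}

# --- genotype generation -----------------------------------------------------

#' Generate a synthetic genotype matrix (VCF-ready)
#'
#' Plants SNPs, InDels and microsatellite-length variants on the synthetic
#' genome. Per-variant MAF is drawn from a scaled Beta (or fixed via the
#' design); genotypes are Hardy-Weinberg draws at that frequency; missingness
#' is Bernoulli per genotype, optionally scaled per sample inversely to
#' realized yields. SSR variants are placed at planted microsatellite tracts
#' as one-unit insertions/deletions (anchored VCF-style on the base before
#' the tract); ten percent of SNPs are concentrated in one 1-kb window,
#' recorded as the variant hotspot truth.
#'
#' @param sg A `synthetic_genome` (or a design, generating the genome).
#' @param yields Optional `data.table` sample/pairs from [gen_reads()] used
#'   for coverage-linked missingness; when absent, sample names are
#'   generated from the design layout and missingness is uniform.
#' @param seed Optional integer overriding the genotype-stage seed (default
#'   `design$seed + 2`).
#' @return List of class `synthetic_genotypes`: `matrix`
#'   (a [genotype_matrix()]), `truth` (`data.table` per variant: type,
#'   maf, position, ssr motif where relevant), `variant_hotspot`
#'   (chrom/start/end), `design`.
#' @export
gen_genotypes <- function(sg, yields = NULL, seed = NULL) {
  if (inherits(sg, "synthetic_design")) sg <- gen_genome(sg)
  stopifnot(inherits(sg, "synthetic_genome"))
  design <- sg$design
  if (is.null(seed)) seed <- design$seed + 2L
  withr::with_seed(as.integer(seed),
                   .gen_genotypes_impl(sg, design, yields))
}

.gen_genotypes_impl <- function(sg, design, yields) {
  genome <- sg$genome
  chrom_names <- names(genome)
  chrom_len <- Biostrings::width(genome)[1L]
  n_samples <- design$n_pools * design$samples_per_pool
  samples <- if (!is.null(yields)) yields$sample else
    sprintf("S%03d", seq_len(n_samples))
  n_s <- length(samples)

  base_at <- function(chrom, p) {
    as.character(Biostrings::subseq(genome[[which(chrom_names == chrom)]],
                                    p, p))
  }
  seq_at <- function(chrom, p, q) {
    as.character(Biostrings::subseq(genome[[which(chrom_names == chrom)]],
                                    p, q))
  }

  rows <- list()
  # SNPs: 90% uniform, 10% in a dense 1-kb hotspot window
  n_hot <- as.integer(round(0.1 * design$n_snp))
  hot_chrom <- chrom_names[length(chrom_names)]
  hot_start <- as.integer(round(chrom_len * 0.25))
  hot_start <- (hot_start %/% 1000L) * 1000L   # align to a 1-kb window
  variant_hotspot <- data.table::data.table(
    chrom = hot_chrom, start = hot_start, end = hot_start + 1000L)
  snp_pos <- c(
    sample.int(chrom_len - 100L, design$n_snp - n_hot) + 50L,
    hot_start + sample.int(1000L, n_hot))
  snp_chrom <- c(sample(chrom_names, design$n_snp - n_hot, replace = TRUE),
                 rep(hot_chrom, n_hot))
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(design$n_snp)) {
    ref <- base_at(snp_chrom[i], snp_pos[i])
    alt <- if (stats::runif(1) < design$snp_transition_prob) {
      transition_of[[ref]]
    } else {
      sample(setdiff(c("A", "C", "G", "T"),
                     c(ref, transition_of[[ref]])), 1L)
    }
    rows[[length(rows) + 1L]] <- list(chrom = snp_chrom[i],
                                      pos = snp_pos[i], ref = ref,
                                      alt = list(alt), type = "SNP",
                                      motif = NA_character_)
  }
  # InDels: length differences 1..31 with mode 1
  if (design$n_indel > 0L) {
    d <- pmin(31L, 1L + stats::rgeom(design$n_indel, 0.45))
    ipos <- sample.int(chrom_len - 200L, design$n_indel) + 100L
    ichrom <- sample(chrom_names, design$n_indel, replace = TRUE)
    is_del <- sample(c(TRUE, FALSE), design$n_indel, replace = TRUE)
    for (i in seq_len(design$n_indel)) {
      if (is_del[i]) {
        ref <- seq_at(ichrom[i], ipos[i], ipos[i] + d[i])
        alt <- substr(ref, 1L, 1L)
      } else {
        ref <- base_at(ichrom[i], ipos[i])
        alt <- paste0(ref, paste(.random_chars(d[i], design$gc),
                                 collapse = ""))
      }
      rows[[length(rows) + 1L]] <- list(chrom = ichrom[i], pos = ipos[i],
                                        ref = ref, alt = list(alt),
                                        type = "InDel",
                                        motif = NA_character_)
    }
  }
  # SSR variants: one-unit length changes at planted tracts
  n_ssr <- min(design$n_ssr_variants, nrow(sg$ssr_tracts))
  if (n_ssr > 0L) {
    tr <- sg$ssr_tracts[sample.int(nrow(sg$ssr_tracts), n_ssr), ]
    for (i in seq_len(n_ssr)) {
      anchor_pos <- tr$start[i] - 1L
      if (anchor_pos < 1L) next
      unit <- tr$motif[i]
      anchor <- base_at(tr$chrom[i], anchor_pos)
      if (stats::runif(1) < 0.5) {        # deletion of one unit
        ref <- paste0(anchor, unit)
        alt <- anchor
      } else {                            # insertion of one unit
        ref <- anchor
        alt <- paste0(anchor, unit)
      }
      rows[[length(rows) + 1L]] <- list(chrom = tr$chrom[i],
                                        pos = anchor_pos, ref = ref,
                                        alt = list(alt), type = "SSR",
                                        motif = unit)
    }
  }

  n_var <- length(rows)
  chrom <- vapply(rows, `[[`, "", "chrom")
  pos <- vapply(rows, function(r) as.integer(r$pos), 0L)
  ref <- vapply(rows, `[[`, "", "ref")
  alt <- lapply(rows, function(r) unlist(r$alt))
  type <- vapply(rows, `[[`, "", "type")
  motif <- vapply(rows, `[[`, "", "motif")

  maf <- if (!is.null(design$maf_fixed)) rep(design$maf_fixed, n_var)
         else 0.5 * stats::rbeta(n_var, design$maf_shape1, design$maf_shape2)
  a1 <- matrix(stats::rbinom(n_var * n_s, 1L, rep(maf, n_s)),
               nrow = n_var, ncol = n_s)
  a2 <- matrix(stats::rbinom(n_var * n_s, 1L, rep(maf, n_s)),
               nrow = n_var, ncol = n_s)
  # missingness
  miss_rate_s <- rep(design$missing_rate, n_s)
  if (design$coverage_linked_missingness && !is.null(yields)) {
    w <- mean(yields$pairs) / pmax(yields$pairs, 1)
    miss_rate_s <- pmin(0.95, design$missing_rate * w / mean(w))
  }
  miss <- matrix(stats::rbinom(n_var * n_s, 1L,
                               rep(miss_rate_s, each = n_var)) == 1L,
                 nrow = n_var, ncol = n_s)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_

  ord <- order(match(chrom, chrom_names), pos)
  gm <- genotype_matrix(chrom[ord], pos[ord], ref[ord], alt[ord],
                        a1[ord, , drop = FALSE], a2[ord, , drop = FALSE],
                        samples, var_type = type[ord])
  truth <- data.table::data.table(chrom = chrom[ord], pos = pos[ord],
                                  type = type[ord], maf = maf[ord],
                                  motif = motif[ord])
  structure(list(matrix = gm, truth = truth,
                 variant_hotspot = variant_hotspot, design = design),
            class = "synthetic_genotypes")
}

#' @export
print.synthetic_genotypes <- function(x, ...) {
  print(x$matrix)
  invisible(x)
}

#' Write a full synthetic dataset to disk
#'
#' Materializes the generator outputs in plain-text formats: genome FASTA,
#' alignments in the interval-TSV dialect (and optionally per-sample SAM),
#' pool map TSV, VCF, truth tables (BED/TSV) and the design echoed as JSON
#' with its seed.
#'
#' @param design A [synthetic_design()].
#' @param dir Output directory (created).
#' @param sam Also write per-sample SAM files.
#' @return Invisible list of generated objects (genome, reads, genotypes).
#' @export
write_synthetic_dataset <- function(design, dir, sam = FALSE) {
  stopifnot(inherits(design, "synthetic_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sg <- gen_genome(design)
  rd <- gen_reads(sg)
  gt <- gen_genotypes(sg, yields = rd$yields)
  Biostrings::writeXStringSet(sg$genome, file.path(dir, "genome.fa"))
  write_alignment_tsv(rd$alignments, file.path(dir, "alignments.tsv"))
  data.table::fwrite(
    data.table::data.table(sample = names(rd$pool_map),
                           pool = unname(rd$pool_map)),
    file.path(dir, "pools.tsv"), sep = "\t")
  write_vcf_genotypes(gt$matrix, file.path(dir, "variants.vcf"),
                      contigs = stats::setNames(
                        Biostrings::width(sg$genome), names(sg$genome)))
  data.table::fwrite(sg$sites, file.path(dir, "truth_sites.tsv"), sep = "\t")
  data.table::fwrite(sg$loci, file.path(dir, "truth_loci.tsv"), sep = "\t")
  data.table::fwrite(sg$ssr_tracts, file.path(dir, "truth_ssr.tsv"),
                     sep = "\t")
  data.table::fwrite(gt$truth, file.path(dir, "truth_variants.tsv"),
                     sep = "\t")
  jsonlite::write_json(design[names(design)],
                       file.path(dir, "design.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (sam) write_sam_per_sample(rd$alignments, dir)
  invisible(list(genome = sg, reads = rd, genotypes = gt))
}

#' Write per-sample SAM files from an alignment set
#'
#' Minimal valid SAM: header `@SQ` lines plus one alignment line per
#' segment (sequence and quality omitted as `*`, CIGAR `<len>M`).
#'
#' @param x An `alignment_set`.
#' @param dir Output directory.
#' @return Character vector of paths, invisibly.
#' @export
write_sam_per_sample <- function(x, dir) {
  stopifnot(inherits(x, "alignment_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(x$seqlengths),
                   as.integer(x$seqlengths)))
  paths <- character(0)
  for (s in unique(x$segments$sample)) {
    seg <- x$segments[x$segments$sample == s, ]
    data.table::setorderv(seg, c("chrom", "start"))
    lines <- sprintf("%s_%06d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                     s, seq_len(nrow(seg)), seg$chrom, seg$start + 1L,
                     seg$mapq, seg$end - seg$start)
    p <- file.path(dir, paste0(s, ".sam"))
    writeLines(c(hdr, lines), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
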