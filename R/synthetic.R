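# Synthetic-data generators. These emulate the statistical structure the
# analysis stages assume: cohort-structured induction time series with
# multiplicative noise, a genome with TSS-annotated TUs carrying helically
# phased A-tracts, and fold-change tables with planted 5'->3' gradients.
# All generators are pure functions of (scenario, seed).

#' Default induction waveform templates
#'
#' Six closed-form log2-scale waveforms mirroring the response classes seen
#' after topoisomerase induction: (1) damped 24 h cosine peaking at dawn,
#' (2) sustained down-step, (3) inverted 24 h cosine with an initial dip,
#' (4) near-flat low-amplitude oscillation, (5) delayed ramp-up from ~24 h,
#' (6) delayed ramp with a plasmid-like overshoot. All are 0 for t < 0
#' (pre-induction).
#'
#' @return Named list of functions of time (hours) returning log2 ratios.
#' @export
default_waveforms <- function() {
  list(
    dawn_damped_cos = function(t)
      ifelse(t < 0, 0, 1.8 * exp(-t / 36) * cos(2 * pi * t / 24)),
    down_step = function(t)
      ifelse(t < 0, 0, -2.0 * (1 - exp(-t / 3))),
    dip_inverted_cos = function(t)
      ifelse(t < 0, 0, -1.8 * exp(-t / 36) * cos(2 * pi * t / 24)),
    near_flat = function(t)
      ifelse(t < 0, 0, 0.35 * sin(2 * pi * t / 24 + 1)),
    late_ramp = function(t)
      ifelse(t < 24, 0, 1.6 * (1 - exp(-(t - 24) / 10))),
    overshoot = function(t)
      ifelse(t < 12, 0,
             3.0 * (1 - exp(-(t - 12) / 5)) * exp(-(t - 12) / 40))
  )
}

#' Default sampling times of the induction series
#'
#' Sixteen time points: two pre-induction samples (-24 h and -35 min) and
#' fourteen post-induction samples from 5 min to 72 h. Clustering uses
#' samples 2..16 (the 15-sample series from -35 min onward); the
#' immediate-response statistics use samples 1:2 vs 3:4.
#'
#' @return Numeric vector of times in hours.
#' @export
default_times <- function() {
  c(-24, -35 / 60, 5 / 60, 20 / 60, 1, 2, 3, 5, 8, 12, 16, 24, 36, 48,
    60, 72)
}

#' Time-series scenario
#'
#' @param cohorts data.frame with columns `name`, `n_genes`, `baseline_meanlog`,
#'   `baseline_sdlog`, plus a parallel list of waveform functions in
#'   `waveforms`; defaults to the six [default_waveforms()] cohorts with
#'   sizes 220, 190, 160, 120, 120, 90 (~900 genes).
#' @param waveforms named list of waveform functions, one per cohort.
#' @param times sampling times (hours), strictly increasing, at least two
#'   pre-induction (< 0) points.
#' @param noise_sd standard deviation of Gaussian noise on the natural-log
#'   scale (multiplicative lognormal noise on TPM).
#' @param seed integer seed; mandatory.
#' @return A list of class `timeseries_scenario`.
#' @export
timeseries_scenario <- function(cohorts = NULL, waveforms = default_waveforms(),
                                times = default_times(),
                                noise_sd = 0.15, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(cohorts)) {
    cohorts <- data.frame(
      name = names(waveforms),
      n_genes = c(220L, 190L, 160L, 120L, 120L, 90L)[seq_along(waveforms)],
      baseline_meanlog = rep(log(50), length(waveforms)),
      baseline_sdlog = rep(1, length(waveforms)),
      stringsAsFactors = FALSE)
  }
  if (any(cohorts$n_genes < 1)) stop("n_genes must be >= 1 per cohort")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (sum(times < 0) < 2) stop("need >= 2 pre-induction (t < 0) times")
  if (!setequal(names(waveforms), cohorts$name))
    stop("waveforms must be named by cohort")
  structure(list(cohorts = cohorts, waveforms = waveforms, times = times,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "timeseries_scenario")
}

#' Simulate a cohort-structured induction time series
#'
#' Gene g in cohort c gets `TPM(t) = baseline_g * 2^w_c(t) * exp(eps)`,
#' `eps ~ N(0, noise_sd^2)`, with baselines drawn lognormally per cohort.
#'
#' @param scenario a [timeseries_scenario].
#' @return List with `matrix` (an [expression_matrix] in TPM) and `truth`
#'   (named character vector gene -> cohort, the planted classification).
#' @export
simulate_timeseries <- function(scenario) {
  stopifnot(inherits(scenario, "timeseries_scenario"))
  set.seed(scenario$seed)
  times <- scenario$times
  rows <- list(); truth <- character(0)
  for (i in seq_len(nrow(scenario$cohorts))) {
    co <- scenario$cohorts[i, ]
    w <- scenario$waveforms[[co$name]](times)
    base <- rlnorm(co$n_genes, co$baseline_meanlog, co$baseline_sdlog)
    eps <- matrix(rnorm(co$n_genes * length(times), 0, scenario$noise_sd),
                  nrow = co$n_genes)
    vals <- base * 2^matrix(w, co$n_genes, length(times), byrow = TRUE) *
      exp(eps)
    rownames(vals) <- sprintf("%s_g%04d", co$name, seq_len(co$n_genes))
    rows[[i]] <- vals
    truth <- c(truth, setNames(rep(co$name, co$n_genes), rownames(vals)))
  }
  vals <- do.call(rbind, rows)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_along(times)),
                        time_h = times)
  list(matrix = expression_matrix(vals, samples, unit = "TPM"),
       truth = truth)
}

#' Promoter scenario
#'
#' Describes a synthetic genome of TSS-annotated transcription units with
#' helically phased A-tract motifs planted upstream of the TSS.
#'
#' @param n_tu number of transcription units.
#' @param upstream,downstream window extent around each TSS (nt).
#' @param gc background G+C fraction.
#' @param anchor relative position of the most-downstream planted A-tract
#'   start (default -10, the position of the maximal observed peak).
#' @param pitch planting period in bp (default 10.5, the DNA helical pitch).
#' @param n_repeats planted tracts per promoter (anchor plus upstream
#'   repeats at multiples of the pitch).
#' @param plant_prob fraction of TUs carrying the pattern.
#' @param repeat_decay probability that upstream repeat j (j >= 1) is
#'   present, geometric in j: repeat j is planted with probability
#'   `repeat_decay^j`. The anchor (j = 0) is always planted in a selected
#'   TU. Models the attenuation of phased peaks away from the TSS.
#' @param jitter_offsets,jitter_probs discrete distribution of a
#'   per-promoter positional jitter (bp) added to all planting positions
#'   of a TU; models the variable phase of the A-tract ladder relative to
#'   the TSS between promoters while preserving the helical spacing
#'   within each promoter.
#' @param gap spacer between tiled TUs (nt).
#' @param seed integer seed; mandatory.
#' @return A list of class `promoter_scenario`.
#' @export
promoter_scenario <- function(n_tu = 300L, upstream = 100L, downstream = 50L,
                              gc = 0.48, anchor = -10, pitch = 10.5,
                              n_repeats = 3L, plant_prob = 0.8,
                              repeat_decay = 0.75,
                              jitter_offsets = -2:2,
                              jitter_probs = c(0.1, 0.2, 0.4, 0.2, 0.1),
                              gap = 20L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (plant_prob < 0 || plant_prob > 1) stop("plant_prob must be in [0,1]")
  if (pitch <= 0) stop("pitch must be > 0")
  if (anchor < -upstream || anchor >= downstream)
    stop("anchor outside window")
  if (length(jitter_offsets) != length(jitter_probs) ||
      abs(sum(jitter_probs) - 1) > 1e-12)
    stop("jitter_probs must sum to 1 and match jitter_offsets")
  structure(list(n_tu = as.integer(n_tu), upstream = as.integer(upstream),
                 downstream = as.integer(downstream), gc = gc,
                 anchor = anchor, pitch = pitch,
                 n_repeats = as.integer(n_repeats),
                 plant_prob = plant_prob, repeat_decay = repeat_decay,
                 jitter_offsets = as.integer(jitter_offsets),
                 jitter_probs = jitter_probs,
                 gap = as.integer(gap), seed = as.integer(seed)),
            class = "promoter_scenario")
}

#' Simulate a genome with tiled, TSS-annotated transcription units
#'
#' Background nucleotides are i.i.d. at the scenario's G+C fraction. TUs
#' are tiled non-overlapping on a single "chromosome" replicon on
#' alternating strands (+ - + - ...), each occupying one window-sized slot,
#' and the TSS of each TU is recorded.
#'
#' @param pscenario a [promoter_scenario].
#' @return List with `genome` (a [genome]) and `tus` (a [tu_table]).
#' @export
simulate_genome <- function(pscenario) {
  stopifnot(inherits(pscenario, "promoter_scenario"))
  set.seed(pscenario$seed)
  U <- pscenario$upstream; D <- pscenario$downstream
  slot <- U + D + pscenario$gap
  len <- pscenario$n_tu * slot + pscenario$gap
  p <- c(A = (1 - pscenario$gc) / 2, C = pscenario$gc / 2,
         G = pscenario$gc / 2, T = (1 - pscenario$gc) / 2)
  seq <- paste(sample(names(p), len, replace = TRUE, prob = p),
               collapse = "")
  idx <- seq_len(pscenario$n_tu)
  strand <- ifelse(idx %% 2L == 1L, "+", "-")
  s0 <- (idx - 1L) * slot + pscenario$gap       # 0-based slot start
  tss <- ifelse(strand == "+", s0 + U, s0 + D - 1L)
  tus <- tu_table(tu_id = sprintf("TU%04d", idx),
                  replicon = rep("chromosome", pscenario$n_tu),
                  replicon_class = rep("chromosome", pscenario$n_tu),
                  strand = strand, tss = tss,
                  genes = lapply(idx, function(i) sprintf("g%04d", i)))
  list(genome = genome(c(chromosome = seq)), tus = tus)
}

# round half away from zero (documented planting-position rule)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

ATRACT4_SET <- c("AAAA", "AAAT", "AATT", "ATTT", "TTTT")

#' Plant helically phased A-tract motifs upstream of TSSs
#'
#' For each selected TU (Bernoulli `plant_prob`), tetranucleotides drawn
#' uniformly from the A-tract(4) set (AAAA, AAAT, AATT, ATTT, TTTT) are
#' written at sense-strand relative positions
#' `round(anchor - j * pitch) + jitter`, j = 0..n_repeats-1 (rounding half
#' away from zero). The anchor tract (j = 0) is always planted; upstream
#' repeats are present with probability `repeat_decay^j`; each selected
#' TU gets one positional jitter shared by all its tracts, so the
#' helical phasing within a promoter is preserved while the ladder's
#' phase relative to the TSS varies between promoters. Minus-strand TUs
#' are edited through
#' the reverse complement at the corresponding genomic coordinates.
#'
#' @param g a [genome].
#' @param tus a [tu_table] (as from [simulate_genome()]).
#' @param pscenario the [promoter_scenario] (its `seed` + 1 drives the
#'   planting so genome and plants are independently reproducible).
#' @return The edited [genome], with attribute `plants`: a data.frame of
#'   realized plantings (`tu_id`, `j`, `rel_start`, `tract`).
#' @export
plant_promoter_motifs <- function(g, tus, pscenario) {
  stopifnot(inherits(pscenario, "promoter_scenario"))
  set.seed(pscenario$seed + 1L)
  U <- pscenario$upstream; D <- pscenario$downstream
  chrs <- as.list(unclass(g))
  plants <- list()
  base_pos <- round_half_away(pscenario$anchor -
                              (seq_len(pscenario$n_repeats) - 1) *
                              pscenario$pitch)
  if (any(base_pos + min(pscenario$jitter_offsets) < -U) ||
      any(base_pos + 3 + max(pscenario$jitter_offsets) >= D))
    stop("planting position outside window")
  for (i in seq_len(nrow(tus))) {
    if (runif(1) > pscenario$plant_prob) next
    jit <- sample(pscenario$jitter_offsets, 1,
                  prob = pscenario$jitter_probs)
    for (j in seq_len(pscenario$n_repeats) - 1L) {
      if (j > 0 && runif(1) > pscenario$repeat_decay^j) next
      rel <- base_pos[j + 1L] + jit
      tract <- sample(ATRACT4_SET, 1)
      chr <- tus$replicon[i]
      if (tus$strand[i] == "+") {
        start0 <- tus$tss[i] + rel              # 0-based start of 4-mer
        substr(chrs[[chr]], start0 + 1L, start0 + 4L) <- tract
      } else {
        # sense positions rel..rel+3 map to genomic tss-rel-3 .. tss-rel
        start0 <- tus$tss[i] - rel - 3L
        substr(chrs[[chr]], start0 + 1L, start0 + 4L) <-
          reverse_complement(tract)
      }
      plants[[length(plants) + 1L]] <-
        data.frame(tu_id = tus$tu_id[i], j = j, rel_start = rel,
                   tract = tract, stringsAsFactors = FALSE)
    }
  }
  out <- genome(unlist(chrs))
  attr(out, "plants") <- if (length(plants)) do.call(rbind, plants)
    else data.frame(tu_id = character(0), j = integer(0),
                    rel_start = integer(0), tract = character(0))
  out
}

#' Gradient scenario
#'
#' @param delta planted log2 gradient between the first and last gene of
#'   each TU (first minus last); recycled over TUs.
#' @param fc_first log2 fold change of the first (5') gene.
#' @param noise_sd per-gene Gaussian noise sd (log2 units).
#' @param contrast contrast name used in the output table.
#' @param seed integer seed; mandatory.
#' @return A list of class `gradient_scenario`.
#' @export
gradient_scenario <- function(delta = 1.5, fc_first = 1.0, noise_sd = 0,
                              contrast = "gyrkd_vs_EVC", seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(!is.finite(delta))) stop("delta must be finite")
  structure(list(delta = delta, fc_first = fc_first, noise_sd = noise_sd,
                 contrast = contrast, seed = as.integer(seed)),
            class = "gradient_scenario")
}

#' Simulate fold changes with planted 5'->3' gradients along TUs
#'
#' Gene k of m in a TU gets
#' `log2fc = fc_first - delta * (k - 1) / (m - 1) + noise`
#' (single-gene TUs get `fc_first + noise`).
#'
#' @param tus a [tu_table].
#' @param gscenario a [gradient_scenario].
#' @return An `fc_table` data.frame (gene_id, contrast, log2fc).
#' @export
simulate_foldchanges <- function(tus, gscenario) {
  stopifnot(inherits(gscenario, "gradient_scenario"))
  set.seed(gscenario$seed)
  delta <- rep_len(gscenario$delta, nrow(tus))
  rows <- lapply(seq_len(nrow(tus)), function(i) {
    gs <- tus$genes[[i]]
    m <- length(gs)
    frac <- if (m == 1) 0 else (seq_len(m) - 1) / (m - 1)
    data.frame(gene_id = gs, contrast = gscenario$contrast,
               log2fc = gscenario$fc_first - delta[i] * frac +
                 rnorm(m, 0, gscenario$noise_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fc_table", "data.frame")
  out
}
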