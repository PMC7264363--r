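# Forward simulator of the surface pre-digestion + biotinylation experiment.
#
# The simulator emulates, per condition (enzyme series x treatment time):
#   1. partial proteolysis of intact cells: Bernoulli cuts at protease sites
#      whose residue is extracellular (the membrane shields I/M residues);
#   2. labelling of accessible primary amines (extracellular protein N-termini,
#      surface-fragment N-termini, accessible extracellular lysines) with the
#      thioacyl / CAMthiopropanoyl remnant masses;
#   3. membrane-prep tryptic digestion in which labelled lysines are never
#      cleaved; the digest acts on the surface fragments, i.e. the tryptic cut
#      set is unioned with the surface pre-digestion cuts;
#   4. emission of modified-peptide observation rows with per-site support
#      counts and score noise, plus piggyback cysteine peptides, deamidation
#      confounders and (optionally) intracellular contaminant labels.
# Full ground truth (site, context, generation cause, support) is recorded.

.AA_FREQ_LOOP <- c(A = 7.0, R = 5.5, N = 4.0, D = 5.0, C = 2.0, Q = 4.0,
                   E = 6.5, G = 7.0, H = 2.5, I = 5.5, L = 9.5, K = 6.0,
                   M = 2.0, F = 4.0, P = 5.0, S = 7.5, T = 5.5, W = 1.5,
                   Y = 3.0, V = 6.5)
.AA_FREQ_TM <- c(A = 10, R = 0.5, N = 1.0, D = 0.5, C = 1.5, Q = 1.0,
                 E = 0.5, G = 6.0, H = 1.0, I = 12, L = 16, K = 0.5,
                 M = 4.0, F = 8.0, P = 2.0, S = 4.0, T = 5.0, W = 2.0,
                 Y = 3.0, V = 12)

#' Simulation parameters
#'
#' Defaults describe the study conditions the simulator emulates: about
#' three quarters of labelled transmembrane proteins single-pass (56/75),
#' an alkylation step converting ~93% of labels to the +145.0198 Da
#' (CAMthiopropanoyl) form, a small intracellular contamination rate so that
#' nearly all observations are biotinylated or cysteine-containing (~97%),
#' and a quarter of proteins without reference topology annotation.
#'
#' @param n_proteins Number of simulated transmembrane proteins.
#' @param single_pass_fraction Fraction of single-pass (type I/II) proteins.
#' @param ecto_len,tm_len,loop_len,tail_len Integer ranges (length 2) for
#'   extracellular domain, membrane segment, inter-segment loop and terminal
#'   tail lengths (residues).
#' @param buried_fraction Fraction of extracellular lysines occluded in the
#'   native surface, accessible only after pre-digestion has cut the protein.
#' @param fraction_unannotated Fraction of proteins whose *reference* topology
#'   annotation is withheld (emitted as all-U) while the true topology still
#'   drives the simulation.
#' @param label_efficiency Probability that an accessible extracellular
#'   primary amine is labelled.
#' @param alkylation_rate Probability a label is observed in the alkylated
#'   (+145.0198 Da) rather than thioacyl (+87.9983 Da) form.
#' @param piggyback_rate Probability an unlabelled cysteine-containing tryptic
#'   peptide of a labelled protein is co-emitted.
#' @param contamination_rate Probability an intracellular primary amine is
#'   (wrongly) reported as labelled.
#' @param support_mean Mean observations per true site and condition.
#' @param deamidation_rate Rate of +0.984 Da deamidation events (per emitted
#'   observation, and per protein for deamidation-only rows).
#' @param score_mu_true,score_mu_false,score_sd Normal score model (truncated
#'   at 0) for confidently identified vs spurious observations; the defaults
#'   straddle the LogProb >= 2 filter.
#' @param block_before_proline Keil rule for both digestion stages.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 75L,
                       single_pass_fraction = 56 / 75,
                       ecto_len = c(80L, 300L),
                       tm_len = c(18L, 25L),
                       loop_len = c(5L, 40L),
                       tail_len = c(5L, 40L),
                       buried_fraction = 0.3,
                       fraction_unannotated = 0.25,
                       label_efficiency = 0.8,
                       alkylation_rate = 0.93,
                       piggyback_rate = 0.15,
                       contamination_rate = 0.02,
                       support_mean = 5,
                       deamidation_rate = 0.05,
                       score_mu_true = 4,
                       score_mu_false = 1.2,
                       score_sd = 1,
                       block_before_proline = TRUE) {
  p <- list(n_proteins = as.integer(n_proteins),
            single_pass_fraction = single_pass_fraction,
            ecto_len = as.integer(ecto_len), tm_len = as.integer(tm_len),
            loop_len = as.integer(loop_len), tail_len = as.integer(tail_len),
            buried_fraction = buried_fraction,
            fraction_unannotated = fraction_unannotated,
            label_efficiency = label_efficiency,
            alkylation_rate = alkylation_rate,
            piggyback_rate = piggyback_rate,
            contamination_rate = contamination_rate,
            support_mean = support_mean,
            deamidation_rate = deamidation_rate,
            score_mu_true = score_mu_true,
            score_mu_false = score_mu_false,
            score_sd = score_sd,
            block_before_proline = isTRUE(block_before_proline))
  probs <- c("single_pass_fraction", "buried_fraction", "fraction_unannotated",
             "label_efficiency", "alkylation_rate", "piggyback_rate",
             "contamination_rate", "deamidation_rate")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("parameter '", nm, "' must be a probability in [0, 1]")
    }
  }
  if (p$n_proteins < 1L) stop("n_proteins must be >= 1")
  if (p$support_mean < 1) stop("support_mean must be >= 1")
  class(p) <- "sim_params"
  p
}

#' Default experimental design
#'
#' The six labelled conditions of the emulated study — chymotrypsin series
#' (non-pre-digested control NPC, 10 min, 20 min) and trypsin series (NPT,
#' 15 min, 25 min) — plus one unlabelled control preparation. Duration labels
#' are opaque strings; the per-condition surface cut probability stands in
#' for digestion time.
#'
#' @param p_cleave Cut probabilities for the two treatment times of each
#'   enzyme (short, long).
#' @param include_unlabelled Include the unlabelled control preparation.
#' @return A data.frame with columns `condition_id`, `enzyme`, `duration`,
#'   `labelled`, `predigested`, `p_cleave`.
#' @export
default_conditions <- function(p_cleave = c(0.3, 0.5),
                               include_unlabelled = TRUE) {
  df <- data.frame(
    enzyme = c(rep("chymotrypsin", 3), rep("trypsin", 3), "none"),
    duration = c("NPC", "10min", "20min", "NPT", "15min", "25min",
                 "unlabelled"),
    labelled = c(rep(TRUE, 6), FALSE),
    predigested = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    p_cleave = c(0, p_cleave[1], p_cleave[2], 0, p_cleave[1], p_cleave[2], 0),
    stringsAsFactors = FALSE)
  if (!include_unlabelled) df <- df[df$labelled, ]
  df$condition_id <- condition_id(df$enzyme, df$duration)
  rownames(df) <- NULL
  df
}

sample_aa <- function(n, freq) {
  if (n <= 0L) return(character(0))
  sample(names(freq), n, replace = TRUE, prob = freq)
}

rint <- function(range) sample(range[1]:range[2], 1L)

# sample() without the scalar-x surprise
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# Support draw: shift + Poisson. True sites are modelled as reproducibly
# sampled — at support_mean >= 3 every true site receives at least the three
# observations that make it reportable; at lower means the draw collapses
# toward single observations so sparse designs under-support sites.
support_draw <- function(n, mean) {
  shift <- max(1L, min(3L, floor(mean)))
  shift + stats::rpois(n, max(0, mean - shift))
}

score_draw <- function(n, mu, sd) pmax(0, stats::rnorm(n, mu, sd))

# minimum peptide length the simulated search engine can identify; also the
# k-mer length whose proteome-wide uniqueness the generator enforces
.MIN_PEP_LEN <- 7L

protein_kmers <- function(s, k = .MIN_PEP_LEN) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Generate a synthetic transmembrane proteome
#'
#' Proteins alternate intracellular (I), membrane (M) and extracellular (O)
#' segments: single-pass type I (N-terminus out) or type II (N-terminus in)
#' with one membrane segment and a large ectodomain, or multi-pass proteins
#' with 2–7 membrane segments and shorter loops. Residues are drawn from
#' loop/membrane-specific compositions; every protein starts with methionine.
#' Proteins are regenerated until every 7-mer is unique proteome-wide, so
#' identifiable peptides map to a single locus. A per-protein set of occluded
#' ("buried") extracellular lysines is drawn once, so accessibility is
#' consistent across conditions.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @return A list of class `sim_proteome`: `proteome` (with true `topology`
#'   and masked `ref_topology`), `buried` (named list of positions), `params`.
#' @export
generate_proteome <- function(params = sim_params(), seed = 1L) {
  gen_one <- function() {
    single <- stats::runif(1) < params$single_pass_fraction
    if (single) {
      type1 <- stats::runif(1) < 0.5
      lens <- c(rint(params$ecto_len), rint(params$tm_len),
                rint(params$tail_len))
      labs <- if (type1) c("O", "M", "I") else c("I", "M", "O")
      if (!type1) lens <- rev(lens)
    } else {
      n_tm <- sample(2:7, 1L)
      side <- sample(c("I", "O"), 1L)
      labs <- character(2L * n_tm + 1L)
      labs[seq(1L, 2L * n_tm + 1L, by = 2L)] <-
        rep(c(side, setdiff(c("I", "O"), side)), length.out = n_tm + 1L)
      labs[seq(2L, 2L * n_tm, by = 2L)] <- "M"
      lens <- integer(length(labs))
      for (k in seq_along(labs)) {
        lens[k] <- if (labs[k] == "M") rint(params$tm_len)
                   else if (k == 1L || k == length(labs)) rint(params$tail_len)
                   else rint(params$loop_len)
      }
    }
    segs <- mapply(function(lab, len) {
      paste(sample_aa(len, if (lab == "M") .AA_FREQ_TM else .AA_FREQ_LOOP),
            collapse = "")
    }, labs, lens)
    s <- paste(segs, collapse = "")
    substr(s, 1L, 1L) <- "M"
    list(seq = s, topo = paste(rep(labs, lens), collapse = ""))
  }
  withr::with_seed(seed, {
    n <- params$n_proteins
    acc <- sprintf("SYN%04d", seq_len(n))
    prots <- replicate(n, gen_one(), simplify = FALSE)
    # regenerate proteins whose 7-mers collide with an earlier protein (or
    # repeat internally) until identifiable peptides are proteome-unique
    for (iter in 1:50) {
      km <- lapply(prots, function(p) protein_kmers(p$seq))
      allk <- unlist(km, use.names = FALSE)
      owner <- rep.int(seq_len(n), lengths(km))
      dup <- duplicated(allk) | duplicated(allk, fromLast = TRUE)
      if (!any(dup)) break
      # per duplicated k-mer: keep the lowest-index owner (unless it repeats
      # the k-mer internally), regenerate every other owner
      redo <- unique(unlist(lapply(split(owner[dup], allk[dup]), function(o) {
        u <- sort(unique(o))
        if (sum(o == u[1]) > 1L) u else u[-1]
      })))
      if (!length(redo)) break
      for (i in redo) prots[[i]] <- gen_one()
    }
    seqs <- vapply(prots, `[[`, "", "seq")
    topo <- vapply(prots, `[[`, "", "topo")
    buried <- lapply(seq_len(n), function(i) {
      aa <- strsplit(seqs[i], "")[[1]]
      ok <- which(aa == "K" & strsplit(topo[i], "")[[1]] == "O")
      ok[stats::runif(length(ok)) < params$buried_fraction]
    })
    prot <- proteome(acc, seqs, topo)
    masked <- stats::runif(n) < params$fraction_unannotated
    prot$ref_topology <- ifelse(masked, strrep("U", nchar(prot$sequence)),
                                prot$topology)
    names(buried) <- acc
    structure(list(proteome = prot, buried = buried, params = params),
              class = "sim_proteome")
  })
}

# Accessible primary amines of one protein under one condition.
# Returns data.frame(position, context, cause).
accessible_amines <- function(aa, topo, buried, cuts, predigested) {
  pos <- integer(0); ctx <- character(0); cause <- character(0)
  if (topo[1] == "O") {
    pos <- 1L; ctx <- "protein_nterm"; cause <- "pre_existing_amine"
  }
  newn <- cuts + 1L
  newn <- newn[topo[newn] == "O"]
  if (length(newn)) {
    pos <- c(pos, newn)
    ctx <- c(ctx, rep("peptide_nterm", length(newn)))
    cause <- c(cause, rep("new_peptide_nterm", length(newn)))
  }
  kpos <- which(aa == "K" & topo == "O")
  exposed <- setdiff(kpos, buried)
  covered <- intersect(kpos, buried)
  if (length(exposed)) {
    pos <- c(pos, exposed)
    ctx <- c(ctx, rep("lysine_sidechain", length(exposed)))
    cause <- c(cause, rep("pre_existing_amine", length(exposed)))
  }
  if (predigested && length(cuts) && length(covered)) {
    pos <- c(pos, covered)
    ctx <- c(ctx, rep("lysine_sidechain", length(covered)))
    cause <- c(cause, rep("uncovered_lysine", length(covered)))
  }
  keep <- !duplicated(pos)
  data.frame(position = pos[keep], context = ctx[keep], cause = cause[keep],
             stringsAsFactors = FALSE)
}

# Peptide carrying a labelled site: the 0-missed-cleavage fragment of the
# membrane digest, extended by up to two missed cleavages while shorter than
# 7 residues (short peptides map ambiguously and are poorly identifiable).
# Extension never crosses a surface pre-digestion cut (the chain is already
# severed there), and an N-terminal label pins the peptide start to the site.
# Returns NULL when no identifiable (>= 6 residue) peptide exists.
site_peptide <- function(seq, frags, position, context, surface_cuts) {
  fi <- findInterval(position, frags$start)
  lo <- fi; hi <- fi
  budget <- 2L
  can_extend <- function(boundary) !(boundary %in% surface_cuts)
  repeat {
    len <- frags$end[hi] - frags$start[lo] + 1L
    if (len >= .MIN_PEP_LEN || budget == 0L) break
    if (hi < nrow(frags) && can_extend(frags$end[hi])) {
      hi <- hi + 1L
    } else if (context == "lysine_sidechain" && lo > 1L &&
                 can_extend(frags$end[lo - 1L])) {
      lo <- lo - 1L
    } else break
    budget <- budget - 1L
  }
  fs <- frags$start[lo]
  fe <- frags$end[hi]
  if (fe - fs + 1L < .MIN_PEP_LEN) return(NULL)
  list(start = fs, end = fe, peptide = substr(seq, fs, fe))
}

#' Simulate one experimental condition
#'
#' Runs the forward model (pre-digestion, labelling, membrane-prep digestion,
#' observation emission) for every protein of a simulated proteome.
#'
#' @param sp A `sim_proteome` from [generate_proteome()].
#' @param condition One row of a [default_conditions()] data.frame.
#' @param seed Integer seed.
#' @return A list with `observations` (see [observation_table()]) and `truth`
#'   (data.frame: `condition_id`, `accession`, `position`, `context`, `cause`,
#'   `mod`, `support`).
#' @export
simulate_condition <- function(sp, condition, seed = 1L) {
  params <- sp$params
  mods <- label_mods()
  cam <- mods$delta_mass[mods$name == "CAMthiopropanoyl"]
  thio <- mods$delta_mass[mods$name == "thioacyl"]
  deam <- deamidation_mass()
  eff <- if (condition$labelled) params$label_efficiency else 0
  srule <- if (condition$predigested) {
    enzyme_rule(condition$enzyme, params$block_before_proline)
  } else NULL
  trule <- enzyme_rule("trypsin", params$block_before_proline)

  withr::with_seed(seed, {
    pep_v <- list(); mods_v <- list(); score_v <- list()
    tru <- list()
    emit <- function(peptide, mods, score) {
      k <- length(pep_v) + 1L
      pep_v[[k]] <<- peptide; mods_v[[k]] <<- mods; score_v[[k]] <<- score
    }
    for (i in seq_len(nrow(sp$proteome))) {
      seq <- sp$proteome$sequence[i]
      accn <- sp$proteome$accession[i]
      aa <- strsplit(seq, "")[[1]]
      topo <- strsplit(sp$proteome$topology[i], "")[[1]]

      # (1) surface pre-digestion, restricted to extracellular residues
      cuts <- integer(0)
      if (condition$predigested) {
        sites <- cleavage_sites(seq, srule)
        sites <- sites[topo[sites] == "O"]
        cuts <- sites[stats::runif(length(sites)) < condition$p_cleave]
      }

      # (2)+(3) accessible amines, labelled with probability label_efficiency
      am <- accessible_amines(aa, topo, sp$buried[[i]], cuts,
                              condition$predigested)
      am <- am[stats::runif(nrow(am)) < eff, , drop = FALSE]

      # intracellular contaminant labels
      ipos <- which(aa == "K" & topo == "I")
      if (topo[1] == "I") ipos <- c(1L, ipos)
      ipos <- ipos[stats::runif(length(ipos)) < params$contamination_rate]
      if (length(ipos)) {
        am <- rbind(am, data.frame(
          position = ipos,
          context = ifelse(ipos == 1L, "protein_nterm", "lysine_sidechain"),
          cause = "contaminant", stringsAsFactors = FALSE))
        am <- am[!duplicated(am$position), , drop = FALSE]
      }
      am$mod <- ifelse(stats::runif(nrow(am)) < params$alkylation_rate,
                       "CAMthiopropanoyl", "thioacyl")

      # (4) membrane-prep tryptic digestion of the surface fragments;
      # labelled lysine side chains are never cleaved
      blockedK <- am$position[am$context == "lysine_sidechain"]
      tcuts <- cleavage_sites(seq, trule, blockedK)
      frags <- fragments_from_cuts(seq, sort(union(tcuts, cuts)))

      # (5)+(6) emit supported observations per labelled site; sites whose
      # peptide is too short to identify are unobservable and dropped from
      # the ground truth as well. Pre-existing amines must additionally be
      # detectable in the undigested context (tryptic digest with all exposed
      # lysines label-blocked): a site whose detectability would arise purely
      # from a pre-digestion-altered missed-cleavage pattern is not counted
      # as a genuine digestion-gained site.
      if (nrow(am)) {
        peps <- lapply(seq_len(nrow(am)), function(j) {
          site_peptide(seq, frags, am$position[j], am$context[j], cuts)
        })
        observable <- !vapply(peps, is.null, logical(1))
        pre <- which(am$cause == "pre_existing_amine" & observable)
        if (length(pre) && condition$predigested) {
          exposedK <- setdiff(which(aa == "K" & topo == "O"), sp$buried[[i]])
          frags0 <- fragments_from_cuts(
            seq, cleavage_sites(seq, trule, exposedK))
          obs0 <- vapply(pre, function(j) {
            !is.null(site_peptide(seq, frags0, am$position[j],
                                  am$context[j], integer(0)))
          }, logical(1))
          observable[pre[!obs0]] <- FALSE
        }
        am <- am[observable, , drop = FALSE]
        peps <- peps[observable]
      }
      if (nrow(am)) {
        am$support <- support_draw(nrow(am), params$support_mean)
        am$support_conf <- 0L
        for (j in seq_len(nrow(am))) {
          pep <- peps[[j]]
          mpos <- if (am$context[j] == "lysine_sidechain") {
            am$position[j] - pep$start + 1L
          } else 0L
          mmass <- if (am$mod[j] == "CAMthiopropanoyl") cam else thio
          mu <- if (am$cause[j] == "contaminant") params$score_mu_false
                else params$score_mu_true
          s <- am$support[j]
          sc <- score_draw(s, mu, params$score_sd)
          am$support_conf[j] <- sum(sc >= 2)
          mstr <- rep(format_mods(mpos, mmass), s)
          dm <- which(stats::runif(s) < params$deamidation_rate)
          if (length(dm)) {
            npos <- setdiff(which(strsplit(pep$peptide, "")[[1]] == "N"),
                            mpos)
            if (length(npos)) {
              picks <- resample(npos, length(dm), replace = TRUE)
              mstr[dm] <- paste(mstr[dm], format_mods_each(picks, deam),
                                sep = ";")
            }
          }
          emit(rep(pep$peptide, s), mstr, sc)
        }
        am$condition_id <- condition$condition_id
        am$accession <- accn
        tru[[length(tru) + 1L]] <-
          am[, c("condition_id", "accession", "position", "context",
                 "cause", "mod", "support", "support_conf")]
      }

      # (7) piggyback cysteine peptides and deamidation-only confounders
      if (nrow(am)) {
        base <- fragments_from_cuts(seq, tcuts)
        cand <- which(grepl("C", base$sequence, fixed = TRUE) &
                        nchar(base$sequence) >= .MIN_PEP_LEN)
        cand <- cand[!vapply(cand, function(k) {
          any(am$position >= base$start[k] & am$position <= base$end[k])
        }, logical(1))]
        take <- cand[stats::runif(length(cand)) < params$piggyback_rate]
        for (k in take) {
          s <- 1L + stats::rpois(1, 0.5)
          emit(rep(base$sequence[k], s), rep("", s),
               score_draw(s, params$score_mu_true, params$score_sd))
        }
        if (stats::runif(1) < params$deamidation_rate) {
          dc <- which(grepl("N", base$sequence, fixed = TRUE) &
                        nchar(base$sequence) >= .MIN_PEP_LEN)
          if (length(dc)) {
            k <- resample(dc, 1L)
            npos <- which(strsplit(base$sequence[k], "")[[1]] == "N")
            emit(base$sequence[k], format_mods(resample(npos, 1L), deam),
                 score_draw(1L, params$score_mu_true, params$score_sd))
          }
        }
      }
    }
    pep_all <- unlist(pep_v, use.names = FALSE)
    if (is.null(pep_all)) pep_all <- character(0)
    mods_all <- unlist(mods_v, use.names = FALSE)
    if (is.null(mods_all)) mods_all <- character(0)
    score_all <- unlist(score_v, use.names = FALSE)
    if (is.null(score_all)) score_all <- numeric(0)
    truth <- if (length(tru)) do.call(rbind, tru) else
      data.frame(condition_id = character(0), accession = character(0),
                 position = integer(0), context = character(0),
                 cause = character(0), mod = character(0),
                 support = integer(0), support_conf = integer(0),
                 stringsAsFactors = FALSE)
    nobs <- length(pep_all)
    sid <- if (nobs) paste0(condition$condition_id, ".r",
                            sample.int(4L, nobs, replace = TRUE))
           else character(0)
    observations <- observation_table(
      sid, rep(condition$enzyme, nobs), rep(condition$duration, nobs),
      rep(condition$labelled, nobs), pep_all, mods_all, score_all)
    rownames(truth) <- NULL
    list(observations = observations, truth = truth)
  })
}

#' Simulate a full experiment
#'
#' Generates a proteome and simulates every condition of the design.
#'
#' @param params A [sim_params()] list.
#' @param conditions A [default_conditions()]-style design.
#' @param seed Integer master seed; per-condition seeds are derived from it.
#' @return A list of class `surf_sim`: `proteome` (`sim_proteome`),
#'   `observations`, `truth`, `conditions`, `params`, `seed`.
#' @export
simulate_experiment <- function(params = sim_params(),
                                conditions = default_conditions(),
                                seed = 1L) {
  sp <- generate_proteome(params, seed)
  runs <- lapply(seq_len(nrow(conditions)), function(i) {
    simulate_condition(sp, conditions[i, ], seed = seed + i)
  })
  structure(list(
    proteome = sp,
    observations = do.call(rbind, lapply(runs, `[[`, "observations")),
    truth = do.call(rbind, lapply(runs, `[[`, "truth")),
    conditions = conditions, params = params, seed = seed),
    class = "surf_sim")
}

#' Ground-truth called-site sets
#'
#' The non-contaminant ground-truth sites of each condition whose emitted
#' support reaches `min_support` — the set a perfect pipeline recovers under
#' the same support filter. By default support is counted over confidently
#' scored observations (`support_conf`, score at or above the LogProb
#' threshold of 2), since sub-threshold observations are not identifications
#' by the study's own definition; set `confident = FALSE` to count every
#' emitted observation.
#'
#' @param truth Truth data.frame from [simulate_experiment()].
#' @param min_support Support threshold (1 recovers every planted site).
#' @param confident Count only confidently scored observations.
#' @return Named list (by condition) of `"accession:position"` keys.
#' @export
truth_called_sites <- function(truth, min_support = 3L, confident = TRUE) {
  supp <- if (confident && !is.null(truth$support_conf)) truth$support_conf
          else truth$support
  t <- truth[truth$cause != "contaminant" & supp >= min_support, ]
  split(site_key(t$accession, t$position), t$condition_id)
}

#' Write a simulated dataset to disk
#'
#' Emits proteome FASTA, reference-topology TSV, one peptide CSV per
#' condition, ground-truth JSON and a parameter YAML, all re-readable by the
#' package's readers. Output is byte-deterministic for a fixed simulation.
#'
#' @param sim A `surf_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
emit_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- sim$proteome$proteome
  paths <- c(fasta = file.path(dir, "proteome.fasta"),
             topology = file.path(dir, "topology.tsv"),
             truth = file.path(dir, "ground_truth.json"),
             params = file.path(dir, "params.yaml"))
  write_fasta(prot, paths["fasta"])
  ref <- prot
  ref$topology <- ref$ref_topology
  write_topology(ref, paths["topology"])
  jsonlite::write_json(list(truth = sim$truth, seed = sim$seed),
                       paths["truth"], digits = NA, dataframe = "columns")
  yaml::write_yaml(list(params = unclass(sim$params),
                        conditions = sim$conditions, seed = sim$seed),
                   paths["params"])
  for (cid in unique(sim$conditions$condition_id)) {
    p <- file.path(dir, paste0("peptides_", cid, ".csv"))
    write_peptide_table(
      sim$observations[sim$observations$condition_id == cid, ], p)
    paths[paste0("peptides_", cid)] <- p
  }
  invisible(paths)
}

#' Read back a simulated dataset
#'
#' @param dir Directory written by [emit_dataset()].
#' @return A list with `proteome` (topology attached), `observations` and
#'   `truth`.
#' @export
read_dataset <- function(dir) {
  prot <- read_fasta(file.path(dir, "proteome.fasta"))
  prot <- read_topology(file.path(dir, "topology.tsv"), prot)
  peps <- list.files(dir, pattern = "^peptides_.*\\.csv$", full.names = TRUE)
  obs <- do.call(rbind, lapply(sort(peps), read_peptide_table))
  truth <- NULL
  tp <- file.path(dir, "ground_truth.json")
  if (file.exists(tp)) {
    truth <- as.data.frame(jsonlite::read_json(tp,
                                               simplifyVector = TRUE)$truth)
  }
  list(proteome = prot, observations = obs, truth = truth)
}
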