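#' Trio QC and per-pair segregation classification
#'
#' A trio is the PB2 plus the two sister blastomeres of one embryo; jointly
#' they account for all 40 chromatids of the somatic genome. Only embryos
#' whose trio closes that accounting on every chromosome enter cohort
#' statistics, mirroring the inclusion rule that every chromosome must be
#' recoverable from all three samples (failures are typically PB2 DNA
#' degradation or amplification artifacts).
#'
#' @name segregation_analysis
NULL

#' Chromatid copies implied by a content state
#'
#' `ABSENT` carries 0 chromatids, `SINGLE_*`/`RECOMBINANT_SINGLE` carry 1,
#' `BOTH` carries 2; `AMBIGUOUS` is `NA`.
#'
#' @param state Character vector of content states.
#' @return Integer vector of copies (NA for ambiguous states).
#' @export
state_copies <- function(state) {
  out <- rep(NA_integer_, length(state))
  out[state == "ABSENT"] <- 0L
  out[state %in% c("SINGLE_A", "SINGLE_B", "RECOMBINANT_SINGLE")] <- 1L
  out[state == "BOTH"] <- 2L
  out
}

# internal: reshape a profile table (one embryo) into per-chromosome
# states of the three roles
trio_states <- function(profiles, chrom_map) {
  roles <- c("PB2", "BLAST1", "BLAST2")
  miss <- setdiff(roles, unique(profiles$role))
  if (length(miss) > 0L) {
    stop("trio is missing role(s): ", paste(miss, collapse = ", "))
  }
  get <- function(role) {
    p <- profiles[profiles$role == role, ]
    p$content_state[match(chrom_map$chrom, p$chrom)]
  }
  data.frame(chrom = chrom_map$chrom,
             pb2 = get("PB2"), blast1 = get("BLAST1"), blast2 = get("BLAST2"),
             stringsAsFactors = FALSE)
}

#' Trio quality control
#'
#' A trio passes iff (a) the two blastomeres agree on every chromosome's
#' content state, (b) no chromosome in any sample is `AMBIGUOUS`, and
#' (c) chromatid accounting closes on every pair. For hybrid backgrounds
#' closure is literal: PB2 copies + zygote copies = 2. For inbred
#' backgrounds the two homologs are sequence-identical, so copy number is
#' not observable from genotypes and closure reduces to presence: every
#' chromosome must be detected on at least one side (for fertilized
#' embryos, in the zygote, which always carries the sperm homolog).
#'
#' @param profiles Profile table of one embryo ([profile_cohort()] rows
#'   with roles `PB2`, `BLAST1`, `BLAST2`).
#' @param background `"HYBRID"`, `"INBRED"` or `"FERTILIZED_INBRED"`.
#' @param chrom_map A [chromosome_map()].
#' @return List `pass` (flag) and `reasons` (character vector).
#' @export
qc_trio <- function(profiles, background = "HYBRID",
                    chrom_map = mouse_chrom_map()) {
  st <- trio_states(profiles, chrom_map)
  reasons <- character(0)
  disc <- st$chrom[st$blast1 != st$blast2]
  if (length(disc) > 0L) {
    reasons <- c(reasons, paste0("blastomere discordance at ",
                                 paste(disc, collapse = ", ")))
  }
  amb <- st$chrom[st$pb2 == "AMBIGUOUS" | st$blast1 == "AMBIGUOUS" |
                    st$blast2 == "AMBIGUOUS"]
  if (length(amb) > 0L) {
    reasons <- c(reasons, paste0("ambiguous content at ",
                                 paste(amb, collapse = ", ")))
  }
  pb2_c <- state_copies(st$pb2)
  zyg_c <- state_copies(st$blast1)       # zygote = blastomere consensus
  if (background == "HYBRID") {
    open <- st$chrom[is.na(pb2_c) | is.na(zyg_c) | pb2_c + zyg_c != 2L]
  } else {
    open <- st$chrom[is.na(pb2_c) | is.na(zyg_c) | pb2_c + zyg_c < 1L]
    if (background == "FERTILIZED_INBRED") {
      open <- union(open, st$chrom[zyg_c == 0L & !is.na(zyg_c)])
    }
  }
  open <- setdiff(open, disc)
  if (length(open) > 0L) {
    reasons <- c(reasons,
                 sprintf("chromatid accounting open on %d chromosome(s): %s",
                         length(open), paste(open, collapse = ", ")))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Classify segregation of one homolog pair
#'
#' Truth table per background, from the PB2 and zygote content states of a
#' QC-passing trio:
#' * `HYBRID`: opposite single strains -> `PROPER`; (`BOTH`, `ABSENT`) ->
#'   `BOTH_EXTRUDED`; (`ABSENT`, `BOTH`) -> `BOTH_RETAINED`; anything else
#'   `UNDETERMINED`.
#' * `INBRED` (homologs indistinguishable; presence/absence only): both
#'   sides present -> `PROPER`; only PB2 -> `BOTH_EXTRUDED`; only zygote
#'   -> `BOTH_RETAINED`.
#' * `FERTILIZED_INBRED` (somatic strain + sperm strain in the zygote):
#'   PB2 carries the somatic strain and the zygote is heterozygous
#'   (`BOTH`) -> `PROPER`; PB2 absent with heterozygous zygote ->
#'   `BOTH_RETAINED`; PB2 somatic with sperm-only zygote ->
#'   `BOTH_EXTRUDED`.
#'
#' @param chrom Chromosome label (carried into the result).
#' @param pb2_state,zygote_state Content states.
#' @param background Cohort background.
#' @param somatic_strain,sperm_strain Strain letters (`"A"`/`"B"`) or
#'   labels matching the catalog strains, used for `FERTILIZED_INBRED`.
#' @return Data.frame row `chrom`, `verdict`.
#' @export
classify_segregation_pair <- function(chrom, pb2_state, zygote_state,
                                      background = "HYBRID",
                                      somatic_strain = "B",
                                      sperm_strain = "A") {
  verdict <- rep("UNDETERMINED", length(chrom))
  pb2 <- pb2_state
  zyg <- zygote_state
  if (background == "HYBRID") {
    proper <- (pb2 == "SINGLE_A" & zyg == "SINGLE_B") |
      (pb2 == "SINGLE_B" & zyg == "SINGLE_A")
    verdict[proper] <- "PROPER"
    verdict[pb2 == "BOTH" & zyg == "ABSENT"] <- "BOTH_EXTRUDED"
    verdict[pb2 == "ABSENT" & zyg == "BOTH"] <- "BOTH_RETAINED"
  } else if (background == "INBRED") {
    present <- function(s) s %in% c("SINGLE_A", "SINGLE_B", "BOTH",
                                    "RECOMBINANT_SINGLE")
    verdict[present(pb2) & present(zyg)] <- "PROPER"
    verdict[present(pb2) & zyg == "ABSENT"] <- "BOTH_EXTRUDED"
    verdict[pb2 == "ABSENT" & present(zyg)] <- "BOTH_RETAINED"
  } else if (background == "FERTILIZED_INBRED") {
    som <- paste0("SINGLE_", substr(somatic_strain, 1, 1))
    spm <- paste0("SINGLE_", substr(sperm_strain, 1, 1))
    verdict[pb2 == som & zyg == "BOTH"] <- "PROPER"
    verdict[pb2 == "ABSENT" & zyg == "BOTH"] <- "BOTH_RETAINED"
    verdict[pb2 == som & zyg == spm] <- "BOTH_EXTRUDED"
  } else {
    stop("unknown background: ", background)
  }
  data.frame(chrom = chrom, verdict = verdict, stringsAsFactors = FALSE)
}

#' Classify a whole cohort of trios
#'
#' Runs trio QC and per-pair classification for every embryo in a profile
#' table.
#'
#' @param profiles Output of [profile_cohort()] on trio observations
#'   (must carry `embryo_id`).
#' @param background Cohort background.
#' @param chrom_map A [chromosome_map()].
#' @param somatic_strain,sperm_strain See [classify_segregation_pair()];
#'   strain letters `"A"`/`"B"` refer to the catalog's ref/alt strains.
#' @return List: `qc` (data.frame `embryo_id`, `qc_pass`, `reasons`),
#'   `calls` (data.frame `embryo_id`, `chrom`, `verdict` for QC-passing
#'   embryos).
#' @export
classify_cohort <- function(profiles, background = "HYBRID",
                            chrom_map = mouse_chrom_map(),
                            somatic_strain = "B", sperm_strain = "A") {
  stopifnot("embryo_id" %in% names(profiles))
  ids <- unique(profiles$embryo_id)
  qc <- data.frame(embryo_id = ids, qc_pass = NA,
                   reasons = NA_character_, stringsAsFactors = FALSE)
  calls <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- profiles[profiles$embryo_id == ids[i], ]
    q <- qc_trio(p, background, chrom_map)
    qc$qc_pass[i] <- q$pass
    qc$reasons[i] <- paste(q$reasons, collapse = "; ")
    if (q$pass) {
      st <- trio_states(p, chrom_map)
      cl <- classify_segregation_pair(st$chrom, st$pb2, st$blast1,
                                      background, somatic_strain,
                                      sperm_strain)
      cl$embryo_id <- ids[i]
      calls[[i]] <- cl
    }
  }
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), verdict = character(),
                        embryo_id = integer(), stringsAsFactors = FALSE)
  }
  list(qc = qc, calls = calls[, c("embryo_id", "chrom", "verdict")])
}

#' Summarize one embryo's segregation calls
#'
#' @param calls Data.frame of one embryo's per-pair verdicts (`chrom`,
#'   `verdict`); must contain exactly `n_pairs` rows.
#' @param n_pairs Homolog pair count (default 20).
#' @param embryo_id Optional id carried into the result.
#' @return One-row data.frame: `n_proper`, `n_retained_chromatids`
#'   (zygote-side chromatids: 1 per proper pair, 2 per retained pair; `NA`
#'   if any verdict is undetermined), `complete_haploidization`.
#' @export
summarize_embryo <- function(calls, n_pairs = 20L, embryo_id = NA) {
  if (nrow(calls) != n_pairs) {
    stop(sprintf("expected %d segregation calls, got %d", n_pairs,
                 nrow(calls)))
  }
  v <- calls$verdict
  n_proper <- sum(v == "PROPER")
  n_ret <- if (any(v == "UNDETERMINED")) NA_integer_ else {
    sum(v == "PROPER") + 2L * sum(v == "BOTH_RETAINED")
  }
  data.frame(embryo_id = embryo_id, n_proper = n_proper,
             n_retained_chromatids = n_ret,
             complete_haploidization = n_proper == n_pairs,
             stringsAsFactors = FALSE)
}

#' Cohort summary table and report
#'
#' @param calls Per-pair verdicts of all QC-passing embryos
#'   ([classify_cohort()]`$calls`).
#' @param n_pairs Homolog pair count (default 20).
#' @return List: `embryos` (per-embryo summary data.frame) and `stats`
#'   (mean/median/mode of proper pairs and retained chromatids, fraction
#'   of complete haploidization, embryo count).
#' @export
cohort_table <- function(calls, n_pairs = 20L) {
  if (nrow(calls) == 0L) stop("empty cohort: no QC-passing embryos")
  ids <- unique(calls$embryo_id)
  rows <- lapply(ids, function(id) {
    summarize_embryo(calls[calls$embryo_id == id, ], n_pairs, id)
  })
  emb <- do.call(rbind, rows)
  mode_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_integer_)
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])
  }
  stats <- list(n_embryos = length(ids),
                mean_proper = mean(emb$n_proper),
                median_proper = stats::median(emb$n_proper),
                mode_proper = mode_of(emb$n_proper),
                mean_retained = mean(emb$n_retained_chromatids, na.rm = TRUE),
                median_retained = stats::median(emb$n_retained_chromatids,
                                                na.rm = TRUE),
                mode_retained = mode_of(emb$n_retained_chromatids),
                fraction_complete_haploidization =
                  mean(emb$complete_haploidization))
  list(embryos = emb, stats = stats)
}

#' Per-chromosome proper-segregation frequency
#'
#' @param calls Per-pair verdicts of QC-passing embryos.
#' @param chrom_map A [chromosome_map()] (fixes output order; adds
#'   chromosome lengths).
#' @return Data.frame `chrom`, `length_bp`, `n_proper`, `n_embryos`,
#'   `proper_fraction`.
#' @export
per_chromosome_frequency <- function(calls, chrom_map = mouse_chrom_map()) {
  if (nrow(calls) == 0L) stop("empty cohort: no QC-passing embryos")
  n_embryos <- length(unique(calls$embryo_id))
  n_proper <- tapply(calls$verdict == "PROPER", calls$chrom, sum)
  out <- data.frame(chrom = chrom_map$chrom,
                    length_bp = chrom_map$length_bp,
                    n_proper = as.integer(n_proper[chrom_map$chrom]),
                    n_embryos = n_embryos, stringsAsFactors = FALSE)
  out$n_proper[is.na(out$n_proper)] <- 0L
  out$proper_fraction <- out$n_proper / n_embryos
  out
}

#' Retention bias among nonsegregating pairs
#'
#' Among pairs where both homologs went to the same side, counts zygote
#' retention versus PB2 extrusion. A cohort with no nonsegregating pair
#' returns the no-nonsegregation sentinel (`ratio = NA`).
#'
#' @param calls Per-pair verdicts of QC-passing embryos.
#' @return List `both_retained`, `both_extruded`, `ratio`
#'   (retained/extruded, `Inf` if extruded is 0 and retained > 0),
#'   `retained_fraction`, `no_nonsegregation` flag.
#' @export
nonsegregation_bias <- function(calls) {
  if (nrow(calls) == 0L) stop("empty cohort: no QC-passing embryos")
  nr <- sum(calls$verdict == "BOTH_RETAINED")
  ne <- sum(calls$verdict == "BOTH_EXTRUDED")
  if (nr + ne == 0L) {
    return(list(both_retained = 0L, both_extruded = 0L, ratio = NA_real_,
                retained_fraction = NA_real_, no_nonsegregation = TRUE))
  }
  list(both_retained = nr, both_extruded = ne,
       ratio = if (ne == 0L) Inf else nr / ne,
       retained_fraction = nr / (nr + ne),
       no_nonsegregation = FALSE)
}
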