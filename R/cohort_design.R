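# Default cohort designer: builds a serial-biopsy study shape (participants
# on differing immunosuppression arms, ordered biopsies with paired urine,
# planted CD8 clones persisting across time points, urine overlap by
# per-clone shedding plus urine-private clones) as a cohort_config that
# generate_cohort() can emit. Randomness is fully determined by `seed`.

#' Design a longitudinal cohort configuration
#'
#' Builds participants, samples and planted clones emulating a serial
#' kidney-allograft study: each participant contributes `n_timepoints`
#' biopsies (with paired urine samples when `paired_urine`), a mix of
#' expanded (size >= 3) and small clones persisting across random subsets of
#' time points, one CD4 and one gamma/delta clone to exercise lineage
#' exclusion, and urine repertoires formed by per-clone shedding from the
#' same-day biopsy plus urine-private clones.
#'
#' @param seed integer seed driving both the design and the generator
#' @param n_participants number of participants (default 3)
#' @param n_timepoints biopsies per participant (default 3)
#' @param paired_urine emit a urine sample per biopsy day (default TRUE)
#' @param cells_per_sample cells per sample (default 3000)
#' @param n_clones planted CD8 clones per participant (default 40)
#' @param urine_shedding per-clone probability a biopsy clone cell is
#'   recovered in the paired urine (default 0.6, applied binomially per cell)
#' @param n_urine_private urine-only expanded clones per urine sample
#'   (default 2)
#' @param zero_noise if TRUE, all corruption rates are zero
#'   (chain recovery 1, no doublets, no QC outliers) so planted truth is
#'   recovered exactly
#' @param chain_recovery_rate,dual_alpha_rate,doublet_rate,mito_outlier_rate,low_gene_rate
#'   forwarded to [cohort_config()] (ignored where `zero_noise` overrides)
#' @return a validated [cohort_config()]
#' @export
design_cohort <- function(seed, n_participants = 3, n_timepoints = 3,
                          paired_urine = TRUE, cells_per_sample = 3000,
                          n_clones = 40, urine_shedding = 0.6,
                          n_urine_private = 2, zero_noise = FALSE,
                          chain_recovery_rate = 0.90, dual_alpha_rate = 0.08,
                          doublet_rate = 0.01, mito_outlier_rate = 0.03,
                          low_gene_rate = 0.03) {
  set.seed(derive_seed(seed, 999))
  arms <- rep(c("tacrolimus", "belatacept", "iscalimab"),
              length.out = n_participants)
  programs <- c("activated", "exhausted", "resident_memory", "none")
  participants <- lapply(seq_len(n_participants), function(i) {
    pid <- sprintf("P%d", i)
    days <- sort(sample(30:350, n_timepoints))
    srows <- list()
    for (d in days) {
      srows[[length(srows) + 1]] <- data.frame(
        sample_id = sprintf("%s_bx_d%03d", pid, d), compartment = "biopsy",
        post_transplant_day = d, stringsAsFactors = FALSE)
    }
    if (paired_urine) {
      for (d in days) {
        srows[[length(srows) + 1]] <- data.frame(
          sample_id = sprintf("%s_ur_d%03d", pid, d), compartment = "urine",
          post_transplant_day = d, stringsAsFactors = FALSE)
      }
    }
    samples <- do.call(rbind, srows)
    bx_ids <- samples$sample_id[samples$compartment == "biopsy"]
    ur_ids <- samples$sample_id[samples$compartment == "urine"]

    clones <- list()
    used <- character(0)
    draw_receptor <- function(dual) {
      repeat {
        a <- random_cdr3(if (dual) 2 else 1)
        b <- random_cdr3(1)
        k <- clonotype_key(a, b)
        if (!k %in% used) {
          used <<- c(used, k)
          return(list(alpha = a, beta = b))
        }
      }
    }
    for (ci in seq_len(n_clones)) {
      rec <- draw_receptor(stats::runif(1) < dual_alpha_rate)
      expandable <- stats::runif(1) < 0.6
      present_bx <- bx_ids[sort(sample.int(
        length(bx_ids), sample.int(length(bx_ids), 1)))]
      sizes <- integer(0)
      for (s in present_bx) {
        sizes[s] <- if (expandable) 3L + stats::rpois(1, 5) else
          sample(1:2, 1)
      }
      if (paired_urine && urine_shedding > 0) {
        for (s in names(sizes)) {
          d <- samples$post_transplant_day[samples$sample_id == s]
          us <- ur_ids[samples$post_transplant_day[
            match(ur_ids, samples$sample_id)] == d]
          shed <- stats::rbinom(1, sizes[[s]], urine_shedding)
          if (length(us) == 1 && shed > 0) sizes[us] <- shed
        }
      }
      clones[[length(clones) + 1]] <- clone_spec(
        clone_id = sprintf("%s_c%02d", pid, ci),
        alpha_cdr3_nt = rec$alpha, beta_cdr3_nt = rec$beta,
        size_by_sample = sizes,
        phenotype_program = sample(programs, 1, prob = c(.35, .25, .2, .2)),
        lineage = "CD8")
    }
    if (paired_urine && n_urine_private > 0) {
      for (us in ur_ids) {
        for (k in seq_len(n_urine_private)) {
          rec <- draw_receptor(stats::runif(1) < dual_alpha_rate)
          sizes <- stats::setNames(3L + stats::rpois(1, 2), us)
          clones[[length(clones) + 1]] <- clone_spec(
            clone_id = sprintf("%s_%s_u%d", pid, us, k),
            alpha_cdr3_nt = rec$alpha, beta_cdr3_nt = rec$beta,
            size_by_sample = sizes, phenotype_program = "none",
            lineage = "CD8")
        }
      }
    }
    # non-CD8 clones exercising the lineage exclusion downstream
    rec <- draw_receptor(FALSE)
    clones[[length(clones) + 1]] <- clone_spec(
      clone_id = sprintf("%s_cd4", pid), alpha_cdr3_nt = rec$alpha,
      beta_cdr3_nt = rec$beta,
      size_by_sample = stats::setNames(4L, bx_ids[1]),
      phenotype_program = "none", lineage = "CD4")
    rec <- draw_receptor(FALSE)
    clones[[length(clones) + 1]] <- clone_spec(
      clone_id = sprintf("%s_gdt", pid), alpha_cdr3_nt = rec$alpha,
      beta_cdr3_nt = rec$beta,
      size_by_sample = stats::setNames(3L, bx_ids[1]),
      phenotype_program = "none", lineage = "gdT")
    participant_spec(pid, arms[i], samples, clones)
  })
  if (zero_noise) {
    chain_recovery_rate <- 1
    doublet_rate <- 0
    mito_outlier_rate <- 0
    low_gene_rate <- 0
  }
  cohort_config(participants, seed = seed,
                chain_recovery_rate = chain_recovery_rate,
                dual_alpha_rate = dual_alpha_rate,
                doublet_rate = doublet_rate,
                mito_outlier_rate = mito_outlier_rate,
                low_gene_rate = low_gene_rate,
                cells_per_sample = cells_per_sample)
}

#' Design a single-sample cohort for marginal-rate recovery
#'
#' One participant, one biopsy, many small planted CD8 clones whose
#' dual-alpha status is drawn from the single configured `dual_alpha_rate`
#' (as it is for background T cells). This shape makes the generator's
#' marginal rates (paired-chain recovery, dual-alpha frequency) measurable
#' through the pipeline at binomial precision: because every cell of a clone
#' shares its alpha set, the independent unit for the dual-alpha fraction in
#' expanded cells is the clone, so many size-3 clones maximize the effective
#' sample size.
#'
#' @param seed integer seed
#' @param cells_per_sample total cells (default 6000)
#' @param n_expanded_clones planted clones of size 3 (default 150)
#' @param chain_recovery_rate,dual_alpha_rate forwarded to [cohort_config()]
#'   (defaults 0.90 and 0.08)
#' @return a validated [cohort_config()]
#' @export
design_rate_cohort <- function(seed, cells_per_sample = 6000,
                               n_expanded_clones = 150,
                               chain_recovery_rate = 0.90,
                               dual_alpha_rate = 0.08) {
  set.seed(derive_seed(seed, 998))
  sid <- "R1_bx_d100"
  samples <- data.frame(sample_id = sid, compartment = "biopsy",
                        post_transplant_day = 100L,
                        stringsAsFactors = FALSE)
  used <- character(0)
  clones <- lapply(seq_len(n_expanded_clones), function(ci) {
    repeat {
      a <- random_cdr3(if (stats::runif(1) < dual_alpha_rate) 2 else 1)
      b <- random_cdr3(1)
      k <- clonotype_key(a, b)
      if (!k %in% used) {
        used <<- c(used, k)
        break
      }
    }
    clone_spec(clone_id = sprintf("R1_c%03d", ci), alpha_cdr3_nt = a,
               beta_cdr3_nt = b,
               size_by_sample = stats::setNames(3L, sid),
               phenotype_program = "none", lineage = "CD8")
  })
  cohort_config(list(participant_spec("R1", "tacrolimus", samples, clones)),
                seed = seed, chain_recovery_rate = chain_recovery_rate,
                dual_alpha_rate = dual_alpha_rate, doublet_rate = 0.01,
                mito_outlier_rate = 0, low_gene_rate = 0,
                cells_per_sample = cells_per_sample)
}
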