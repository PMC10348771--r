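# Longitudinal clone tracking and biopsy-urine overlap. Clonotype keys are
# matched verbatim across a participant's samples ordered by post-transplant
# day; persistence asks, of the clonotypes expanded at a given sample, how
# many were expanded at an earlier sample of the same compartment.

#' Build clone tracks across a participant's samples
#'
#' One track per clonotype key observed in a participant, restricted by
#' default to keys expanded in at least one sample (the figures' scope);
#' keyless units never form tracks. Output is long-format: one row per
#' (key, sample), including absent samples at size 0, so persistence and
#' overlap are simple filters on the result.
#'
#' @param sample_calls named list: sample_id -> result of
#'   [call_clonotypes()]
#' @param manifest manifest data.frame covering those samples (`sample_id,
#'   participant_id, compartment, post_transplant_day`)
#' @param scope `"expanded_any"` (default: keys expanded somewhere) or
#'   `"all"` (every key observed)
#' @return data.frame: `participant_id, key, sample_id, post_transplant_day,
#'   compartment, size, status` (expanded | unexpanded | absent), plus
#'   `first_expanded_sample` repeated per track row (NA if never expanded)
#' @export
build_tracks <- function(sample_calls, manifest, scope = c("expanded_any", "all")) {
  scope <- match.arg(scope)
  if (anyDuplicated(manifest$sample_id)) {
    stopf("duplicate sample ids in manifest")
  }
  missing <- setdiff(names(sample_calls), manifest$sample_id)
  if (length(missing) > 0) {
    stopf("samples absent from manifest: %s", paste(missing, collapse = ", "))
  }
  man <- manifest[manifest$sample_id %in% names(sample_calls), , drop = FALSE]
  man <- man[order(man$participant_id, man$post_transplant_day,
                   man$compartment, man$sample_id), , drop = FALSE]
  out <- list()
  for (pid in unique(man$participant_id)) {
    pm <- man[man$participant_id == pid, , drop = FALSE]
    tabs <- lapply(pm$sample_id, function(s) calls_table(sample_calls[[s]]))
    names(tabs) <- pm$sample_id
    keys <- unique(unlist(lapply(tabs, function(t) t$key)))
    if (scope == "expanded_any") {
      exp_keys <- unique(unlist(lapply(tabs, function(t)
        t$key[t$status == "expanded"])))
      keys <- intersect(keys, exp_keys)
    }
    if (length(keys) == 0) next
    keys <- sort(keys)
    for (k in keys) {
      size <- vapply(tabs, function(t) {
        i <- match(k, t$key)
        if (is.na(i)) 0 else as.numeric(t$size[i])
      }, numeric(1))
      size <- as.integer(size)
      status <- vapply(tabs, function(t) {
        i <- match(k, t$key)
        if (is.na(i)) "absent" else t$status[i]
      }, character(1))
      exp_idx <- which(status == "expanded")
      first_exp <- if (length(exp_idx) > 0) {
        pm$sample_id[exp_idx[which.min(pm$post_transplant_day[exp_idx])]]
      } else NA_character_
      out[[length(out) + 1]] <- data.frame(
        participant_id = pid, key = k, sample_id = pm$sample_id,
        post_transplant_day = pm$post_transplant_day,
        compartment = pm$compartment, size = size, status = status,
        first_expanded_sample = first_exp, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(participant_id = character(0), key = character(0),
                      sample_id = character(0),
                      post_transplant_day = integer(0),
                      compartment = character(0), size = integer(0),
                      status = character(0),
                      first_expanded_sample = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

calls_table <- function(calls) {
  cl <- calls$clonotypes
  data.frame(key = cl$key, size = cl$size, status = cl$status,
             stringsAsFactors = FALSE)
}

#' Persistence of expanded clonotypes at a sample
#'
#' Among clonotypes expanded at `sample_id`, counts those already seen at an
#' earlier sample (strictly smaller post-transplant day). "Seen" defaults to
#' expanded earlier, matching how the figures track expanded clones; set
#' `prior = "present"` to accept any earlier presence. Earlier samples are
#' restricted to the same compartment unless `same_compartment = FALSE`.
#'
#' @param tracks track table from [build_tracks()]
#' @param sample_id sample to evaluate
#' @param prior `"expanded"` (default) or `"present"`
#' @param same_compartment restrict prior samples to the sample's compartment
#' @return list: `n_expanded_total`, `n_seen_prior`, `pct_prior` (0-100,
#'   half-up to nearest integer; 0 at a first sample)
#' @export
persistence_counts <- function(tracks, sample_id,
                               prior = c("expanded", "present"),
                               same_compartment = TRUE) {
  prior <- match.arg(prior)
  here <- tracks[tracks$sample_id == sample_id, , drop = FALSE]
  if (nrow(here) == 0) {
    return(list(n_expanded_total = 0L, n_seen_prior = 0L, pct_prior = 0))
  }
  day <- here$post_transplant_day[1]
  comp <- here$compartment[1]
  exp_keys <- here$key[here$status == "expanded"]
  earlier <- tracks[tracks$post_transplant_day < day &
                      tracks$key %in% exp_keys, , drop = FALSE]
  if (same_compartment) {
    earlier <- earlier[earlier$compartment == comp, , drop = FALSE]
  }
  seen_status <- if (prior == "expanded") "expanded" else
    c("expanded", "unexpanded")
  seen <- unique(earlier$key[earlier$status %in% seen_status])
  n_tot <- length(exp_keys)
  n_seen <- length(intersect(exp_keys, seen))
  pct <- if (n_tot == 0) 0 else round_half_up(100 * n_seen / n_tot)
  list(n_expanded_total = n_tot, n_seen_prior = n_seen, pct_prior = pct)
}

#' Overlap of expanded clonotype sets between two samples
#'
#' Exact set intersection/differences on clonotype-key equality, e.g. between
#' a biopsy and its paired urine sample.
#'
#' @param keys_a,keys_b character vectors of expanded clonotype keys
#' @param sample_a,sample_b labels carried into the result
#' @return list: `sample_a, sample_b, n_shared_expanded, n_a_only, n_b_only,
#'   shared_keys`
#' @export
overlap <- function(keys_a, keys_b, sample_a = "a", sample_b = "b") {
  a <- unique(keys_a); b <- unique(keys_b)
  shared <- sort(intersect(a, b))
  list(sample_a = sample_a, sample_b = sample_b,
       n_shared_expanded = length(shared),
       n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)),
       shared_keys = shared)
}
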