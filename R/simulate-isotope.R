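# Seeded simulator of an EA-IRMS enrichment time course.

#' Simulate replicate delta-15N measurements for pools over time
#'
#' Takes a table of reported mean +/- SEM delta-15N values per N pool
#' (e.g. RNA, protein, bulk soil, DNA) and per sampling day and draws
#' replicate measurements from normal distributions. The per-replicate
#' standard deviation is reconstructed from the SEM as
#' `sem * sqrt(n_reference)`, where `n_reference` is the replication the
#' SEM was computed from (triplicate incubations by default).
#'
#' @param pools data frame with columns `pool`, `day`, `mean`, `sem`
#'   (delta-15N, per mille).
#' @param n_replicates replicates to draw per pool x day.
#' @param n_reference replication behind the reported SEMs (default 3).
#' @param seed integer seed.
#' @return data frame with columns `pool`, `day`, `replicate`,
#'   `delta_permil`.
#' @export
#' @examples
#' tc <- data.frame(pool = c("RNA", "protein", "bulk", "DNA"), day = 3,
#'                  mean = c(1264, 194, 118, 5), sem = c(370, 9, 6, 3))
#' sim <- simulate_isotope_timecourse(tc, n_replicates = 3, seed = 1)
simulate_isotope_timecourse <- function(pools, n_replicates = 3,
                                        n_reference = 3, seed = 1L) {
  need <- c("pool", "day", "mean", "sem")
  if (!all(need %in% names(pools)))
    stop("pools needs columns: ", paste(need, collapse = ", "))
  if (any(pools$sem < 0)) stop("SEMs must be non-negative")
  stopifnot(n_replicates >= 1, n_reference >= 1)
  set.seed(as.integer(seed))
  sd_rep <- pools$sem * sqrt(n_reference)
  out <- lapply(seq_len(nrow(pools)), function(i) {
    data.frame(pool = pools$pool[i], day = pools$day[i],
               replicate = seq_len(n_replicates),
               delta_permil = stats::rnorm(n_replicates, pools$mean[i],
                                           sd_rep[i]))
  })
  do.call(rbind, out)
}
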