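# Published national reference summaries shipped with the package: the
# per-ecozone spread-day statistics for Canadian fires >= 50 ha, 2001-2021,
# used in worked examples and as arithmetic fixtures for the table-summary
# operations.

#' Ecozone-level reference summaries for Canada (2001–2021)
#'
#' Three per-ecozone tables for Canadian fires of at least 50 ha across the
#' 11 analysis ecozones (Taiga Shield and Boreal Shield split west/east):
#'
#' * `thresholds`: mean (and s.d. over 100 year-resampling replicates) of
#'   the annual 50%-area threshold per FWI System variable;
#' * `percentiles`: percentile rank of those thresholds in the paired
#'   fire-weather distribution;
#' * `rsd_psd`: mean (s.d.) percent of potential spread days realized, for
#'   the three fast-reacting variables under national (`nat_*`) and
#'   ecozone (`ez_*`) thresholds.
#'
#' Summary rows are not included; recompute them with
#' [summarize_ecozone_table()] and [summarize_percentile_table()].
#'
#' @return named list of three data frames.
#' @export
#' @examples
#' ref <- reference_tables()
#' round(mean(ref$thresholds$ffmc_mean), 1)  # 89.1
reference_tables <- function() {
  rd <- function(f) read.delim(system.file("extdata", f,
                                           package = "spreadday"),
                               check.names = FALSE)
  list(thresholds = rd("ecozone_thresholds.tsv"),
       percentiles = rd("ecozone_percentiles.tsv"),
       rsd_psd = rd("ecozone_rsd_psd.tsv"))
}
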