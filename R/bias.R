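#' Ligand-bias estimation from a logEC50 ledger
#'
#' Implements the relative-potency-ratio approach for full agonists
#' measured in parallel pathways. Within each experiment and pathway, the
#' test agonists' logEC50 values are subtracted from the reference
#' agonist's to give normalized potency estimates
#' (`deltaLogEC50 = logEC50(reference agonist) - logEC50(agonist)`);
#' the test pathway's delta is then subtracted from the reference
#' pathway's to give the bias estimate
#' (`deltaDeltaLogEC50 = deltaLogEC50(reference pathway) -
#' deltaLogEC50(test pathway)`). Because all agonists are measured in
#' parallel within an experiment, experiment-specific deltas are formed
#' first and summarized as mean +/- SEM over experiments, with no error
#' propagation across ratios. The reference agonist's deltas are
#' identically zero, hence its bias estimate is zero by construction.
#'
#' @param table data.frame with columns `agonist`, `pathway`,
#'   `experiment`, `logEC50`; every (agonist, pathway) cell must be
#'   present within each experiment.
#' @param referenceAgonist agonist against which potencies are
#'   normalized.
#' @param referencePathway,testPathway the two pathways entering the
#'   bias subtraction.
#' @return A [BiasEstimate-class].
#' @examples
#' tab <- expand.grid(agonist = c("ref", "a"),
#'                    pathway = c("P1", "P2"), experiment = 1:3,
#'                    stringsAsFactors = FALSE)
#' tab$logEC50 <- -9
#' tab$logEC50[tab$agonist == "a" & tab$pathway == "P2"] <- -8.5
#' biasEstimate(tab, "ref", "P1", "P2")
#' @export
biasEstimate <- function(table, referenceAgonist, referencePathway,
                         testPathway) {
  stopifnot(is.data.frame(table),
            all(c("agonist", "pathway", "experiment", "logEC50") %in%
                  names(table)))
  table$agonist <- as.character(table$agonist)
  table$pathway <- as.character(table$pathway)
  if (!referenceAgonist %in% table$agonist)
    stop("reference agonist '", referenceAgonist, "' not in table")
  for (pw in c(referencePathway, testPathway))
    if (!pw %in% table$pathway) stop("pathway '", pw, "' not in table")
  agonists <- unique(table$agonist)
  pathways <- unique(table$pathway)
  experiments <- unique(table$experiment)
  # completeness: every (agonist, pathway) within each experiment
  for (ex in experiments) for (ag in agonists) for (pw in pathways) {
    hit <- table$experiment == ex & table$agonist == ag &
      table$pathway == pw
    if (sum(hit) == 0L)
      stop("missing logEC50 cell: agonist '", ag, "', pathway '", pw,
           "', experiment '", ex, "'")
    if (sum(hit) > 1L)
      stop("duplicated logEC50 cell: agonist '", ag, "', pathway '", pw,
           "', experiment '", ex, "'")
  }
  cell <- function(ex, ag, pw)
    table$logEC50[table$experiment == ex & table$agonist == ag &
                    table$pathway == pw]
  per <- do.call(rbind, lapply(experiments, function(ex) {
    do.call(rbind, lapply(agonists, function(ag) {
      dl <- vapply(pathways, function(pw)
        cell(ex, referenceAgonist, pw) - cell(ex, ag, pw), numeric(1L))
      dd <- dl[[referencePathway]] - dl[[testPathway]]
      data.frame(experiment = ex, agonist = ag, pathway = pathways,
                 deltaLogEC50 = unname(dl), deltaDeltaLogEC50 = dd,
                 row.names = NULL)
    }))
  }))
  ddPerExp <- unique(per[, c("experiment", "agonist",
                             "deltaDeltaLogEC50")])
  summ <- do.call(rbind, lapply(agonists, function(ag) {
    v <- ddPerExp$deltaDeltaLogEC50[ddPerExp$agonist == ag]
    data.frame(agonist = ag, deltaDeltaLogEC50 = mean(v),
               sem = if (length(v) > 1L) .sem(v) else NA_real_,
               nExperiments = length(v))
  }))
  new("BiasEstimate", perExperiment = per, summary = summ,
      referenceAgonist = referenceAgonist,
      referencePathway = referencePathway, testPathway = testPathway)
}
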