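## Bundled membership tables and block-structured overlap fixtures for the
## 30 cortical RSNs of the corticotopy analysis, one per reference system:
## task-based networks (tbn, 6 clusters x 18 units), extended Brodmann areas
## (ba, 7 clusters x 28 units) and Brodmann-area families (baf, 10 clusters
## x 7 units).  The BAF table lists networks 18 and 20 both in the large
## association cluster and as singletons; the bundled resolution keeps each
## in its singleton cluster.

baf_duplicate_resolution <- c("18" = "3", "20" = "4")

#' Bundled RSN cluster-membership tables
#'
#' @param reference `"tbn"`, `"ba"` or `"baf"`.
#' @param resolved For `"baf"`, apply the bundled duplicate resolution
#'   (networks 18 and 20 keep their singleton clusters); default TRUE.
#' @return A [membership_table()].
#' @export
bundled_membership <- function(reference = c("tbn", "ba", "baf"), resolved = TRUE) {
  reference <- match.arg(reference)
  path <- system.file("extdata", "memberships",
                      sprintf("rsn_%s_clusters.tsv", reference),
                      package = "ringscape", mustWork = TRUE)
  tab <- read_membership_table(path)
  if (reference == "baf" && resolved) {
    tab <- resolve_duplicates(tab, baf_duplicate_resolution)
  }
  tab
}

fixture_design <- function(reference) {
  switch(reference,
    tbn = list(
      n_columns = 18L,
      column_names = paste0("TBN", 1:18),
      blocks = NULL,  # contiguous blocks of 3 per cluster
      sensory = paste0("TBN", 1:15)
    ),
    ba = list(
      n_columns = 28L,
      column_names = c("BA17", "BA18", "BA19", "BA7",
                       "BA1", "BA2", "BA3", "BA4",
                       "BA5", "BA6", "BA43", "41*",
                       "BA21", "BA22", "BA37", "20*",
                       "BA39", "BA40", "23*", "32*",
                       "28*", "BA44", "BA45", "BA47",
                       "BA8", "BA9", "BA46", "BA10"),
      blocks = NULL,  # contiguous blocks of 4 per cluster
      sensory = c("BA17", "BA18", "BA19", "BA7",
                  "BA1", "BA2", "BA3", "BA4",
                  "BA5", "BA6", "BA43", "41*",
                  "BA21", "BA22", "BA37", "20*")
    ),
    baf = list(
      n_columns = 7L,
      column_names = paste0("BAF", 1:7),
      ## 10 clusters over 7 columns cannot take disjoint non-empty blocks;
      ## each cluster receives a distinct (possibly overlapping) column set
      ## reflecting its dominant reference families
      blocks = list(
        "1"  = "BAF7",
        "2"  = "BAF6",
        "3"  = c("BAF5", "BAF6"),
        "4"  = c("BAF6", "BAF7"),
        "5"  = "BAF5",
        "6"  = c("BAF1", "BAF2", "BAF4"),
        "7"  = c("BAF2", "BAF3"),
        "8"  = "BAF4",
        "9"  = c("BAF4", "BAF7"),
        "10" = c("BAF2", "BAF7")
      ),
      sensory = c("BAF5", "BAF6", "BAF7")
    ),
    stop_validation("unknown reference '%s'", reference)
  )
}

#' Bundled block-structured overlap fixture
#'
#' Builds the Poisson block fixture encoding the bundled membership table
#' for one reference system: entries inside a cluster's column block are
#' Poisson(`high_mean`), entries outside Poisson(`low_mean`).
#'
#' @inheritParams bundled_membership
#' @param seed Integer seed.
#' @param high_mean,low_mean Poisson block means (defaults 500 / 10).
#' @return An [overlap_matrix()] with attributes `blocks`, `sensory` (column
#'   names flagged sensorimotor) and `table` (the [membership_table()]).
#' @export
bundled_overlap_fixture <- function(reference = c("tbn", "ba", "baf"), seed = 1L,
                                    high_mean = 500, low_mean = 10) {
  reference <- match.arg(reference)
  design <- fixture_design(reference)
  tab <- bundled_membership(reference, resolved = TRUE)
  m <- fixture_overlap_matrix(tab, design$n_columns, high_mean, low_mean, seed,
                              blocks = design$blocks,
                              column_names = design$column_names)
  attr(m, "sensory") <- design$sensory
  attr(m, "table") <- tab
  m
}
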