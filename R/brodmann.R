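## The two Brodmann regroupings used by the corticotopy analysis: a merge of
## small adjacent areas into "extended" areas (starred names), and seven
## anatomo-functional Brodmann-area families (BAF1..BAF7).

ba_merge_rules <- list(
  "20*" = c("BA20", "BA38"),
  "41*" = c("BA41", "BA42"),
  "28*" = c("BA28", "BA34", "BA35", "BA36"),
  "32*" = c("BA32", "BA24", "BA25"),
  "23*" = c("BA23", "BA29", "BA30", "BA31")
)

baf_rules <- list(
  BAF1 = c(10, 11),              # anterior frontal
  BAF2 = c(8, 9, 46),            # superior frontal
  BAF3 = c(44, 45, 47),          # inferior frontal
  BAF4 = c(23, 32),              # cingular (posterior / anterior)
  BAF5 = c(41, 42, 21, 22, 37),  # temporal auditory
  BAF6 = c(2, 3, 4, 5, 6),       # central somatomotor
  BAF7 = c(17, 18, 19)           # occipital visual
)

#' Regroup a Brodmann atlas into extended areas
#'
#' Merges small adjacent Brodmann areas into five extended areas
#' (20* = 20+38, 41* = 41+42, 28* = 28+34+35+36, 32* = 32+24+25,
#' 23* = 23+29+30+31); all other areas pass through unchanged. Applying the
#' regrouping to an already-regrouped atlas is a no-op.
#'
#' @param ba_atlas A [reference_atlas()] whose units are named `BA<k>`.
#' @return A [reference_atlas()] with the merged (starred) units appended
#'   after the pass-through units, in rule order.
#' @export
regroup_brodmann <- function(ba_atlas) {
  stopifnot(inherits(ba_atlas, "reference_atlas"))
  nm <- names(ba_atlas$units)
  if (all(names(ba_merge_rules) %in% nm) &&
      !any(unlist(ba_merge_rules) %in% nm)) {
    return(ba_atlas)  # already regrouped
  }
  consumed <- unlist(ba_merge_rules)
  missing <- setdiff(consumed, nm)
  if (length(missing) > 0L) {
    stop_config("Brodmann regrouping needs missing area(s): %s",
                paste(missing, collapse = ", "))
  }
  keep <- ba_atlas$units[setdiff(nm, consumed)]
  merged <- lapply(ba_merge_rules, function(members) {
    mask_union(ba_atlas$units[members])
  })
  reference_atlas(ba_atlas$grid, c(keep, merged))
}

#' Group Brodmann areas into the seven anatomo-functional families
#'
#' BAF1 anterior frontal (10, 11); BAF2 superior frontal (8, 9, 46); BAF3
#' inferior frontal (44, 45, 47); BAF4 cingular (23, 32); BAF5 temporal
#' auditory (41, 42, 21, 22, 37); BAF6 central somatomotor (2..6); BAF7
#' occipital visual (17, 18, 19). Areas in no family are excluded with a
#' message.
#'
#' @param ba_atlas A [reference_atlas()] whose units are named `BA<k>`
#'   (un-regrouped Brodmann areas).
#' @return A [reference_atlas()] with units BAF1..BAF7.
#' @export
brodmann_families <- function(ba_atlas) {
  stopifnot(inherits(ba_atlas, "reference_atlas"))
  nm <- names(ba_atlas$units)
  needed <- paste0("BA", unlist(baf_rules))
  missing <- setdiff(needed, nm)
  if (length(missing) > 0L) {
    stop_config("Brodmann families need missing area(s): %s",
                paste(missing, collapse = ", "))
  }
  units <- lapply(baf_rules, function(ks) mask_union(ba_atlas$units[paste0("BA", ks)]))
  left_out <- setdiff(nm, needed)
  if (length(left_out) > 0L) {
    message("areas not in any family, excluded: ", paste(left_out, collapse = ", "))
  }
  reference_atlas(ba_atlas$grid, units)
}
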