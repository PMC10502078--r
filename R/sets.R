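#' Shared-SNP set analysis across food-specific GRSs
#'
#' Exact set algebra over the rsID subsets of several food-specific GRSs:
#' the union, the all-way intersection, a membership matrix, and the count of
#' SNPs in every exclusive Venn region (each non-empty combination of
#' memberships).
#'
#' @param fgrsList a named list of [FoodGRS-class] objects or of character
#'   rsID vectors; unnamed `FoodGRS` entries are named by their food item.
#' @return A list with:
#'   \describe{
#'     \item{membership}{logical matrix, union rsIDs x foods.}
#'     \item{union}{character, all rsIDs involved.}
#'     \item{intersection}{character, rsIDs present in every list.}
#'     \item{regions}{data.frame of exclusive Venn regions: the membership
#'       pattern (foods joined by `&`), `count` and the rsIDs.}
#'   }
#' @examples
#' lists <- publishedFoodGrsSnps()
#' four <- lists[c("pizza", "sweets_chocolate", "sugary_juice_drink", "hamburger_hotdog")]
#' res <- sharedSnpAnalysis(four)
#' length(res$union) # 15
#' length(res$intersection) # 5
#' @export
sharedSnpAnalysis <- function(fgrsList) {
  if (length(fgrsList) < 1) stop("need at least one food-specific GRS", call. = FALSE)
  sets <- lapply(fgrsList, function(x) {
    if (is(x, "FoodGRS")) rsids(x) else as.character(x)
  })
  nm <- names(fgrsList)
  if (is.null(nm)) nm <- rep("", length(sets))
  for (i in seq_along(sets)) {
    if (!nzchar(nm[i])) {
      nm[i] <- if (is(fgrsList[[i]], "FoodGRS")) {
        foodItem(fgrsList[[i]])
      } else {
        paste0("set", i)
      }
    }
    if (anyDuplicated(sets[[i]])) {
      stop("duplicated rsIDs in set '", nm[i], "'", call. = FALSE)
    }
  }
  names(sets) <- nm
  all_ids <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) all_ids %in% s,
    logical(length(all_ids))
  )
  membership <- matrix(membership,
    nrow = length(all_ids),
    dimnames = list(all_ids, nm)
  )
  inter <- all_ids[rowSums(membership) == length(sets)]
  pattern <- apply(membership, 1, function(row) {
    paste(nm[row], collapse = " & ")
  })
  regions <- do.call(rbind, lapply(unique(pattern), function(pat) {
    ids <- all_ids[pattern == pat]
    data.frame(
      region = pat, count = length(ids),
      rsids = paste(ids, collapse = ","), stringsAsFactors = FALSE
    )
  }))
  rownames(regions) <- NULL
  list(
    membership = membership,
    union = all_ids,
    intersection = inter,
    regions = regions
  )
}
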