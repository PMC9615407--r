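# Medication-derived multimorbidity counting. Concomitant-medication
# tokens are mapped to broad chronic-condition categories (21 by
# default); the multimorbidity count is the number of distinct categories
# with at least one qualifying medication.

#' The 21 default comorbidity categories
#'
#' Broad chronic-condition categories identifiable from medication use:
#' cardiovascular disease, chronic pain, arthritis, affective disorders,
#' acid-related disorders, asthma/COPD, diabetes mellitus, osteoporosis,
#' thyroid disease, thromboembolic disease, inflammatory conditions,
#' benign prostatic hyperplasia, gout, glaucoma, urinary incontinence,
#' erectile dysfunction, psychotic disorders, epilepsy, migraine,
#' parkinsonism and dementia.
#'
#' @return character vector of 21 category identifiers.
#' @export
comorbidity_categories <- function() {
  c("cardiovascular_disease", "chronic_pain", "arthritis",
    "affective_disorders", "acid_related_disorders", "asthma_copd",
    "diabetes_mellitus", "osteoporosis", "thyroid_disease",
    "thromboembolic_disease", "inflammatory_conditions",
    "benign_prostatic_hyperplasia", "gout", "glaucoma",
    "urinary_incontinence", "erectile_dysfunction", "psychotic_disorders",
    "epilepsy", "migraine", "parkinsonism", "dementia")
}

#' Load a medication-to-comorbidity mapping
#'
#' Reads a TSV with columns `token`, `category`, `action`
#' (`include`/`exclude`). Excluded tokens never contribute to any
#' category (used for drugs with too many indications to be informative,
#' e.g. tricyclic antidepressants). The mapping must be many-to-one: a
#' token mapped to two categories, or both included and excluded, is
#' rejected. The real-world drug-code lists sit behind governed data
#' access; the package ships a clearly labelled synthetic mapping
#' (`system.file("extdata", "comorbidity_map_synthetic.tsv", package =
#' "saerep")`) for testing and simulation.
#'
#' @param path path to the mapping TSV.
#' @return an object of class `comorbidity_map`: `categories` (ordered),
#'   `mapping` (named character: token -> category), `exclusions`
#'   (character vector of tokens).
#' @export
load_comorbidity_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(structure(list(categories = character(0),
                          mapping = stats::setNames(character(0), character(0)),
                          exclusions = character(0)),
                     class = "comorbidity_map"))
  }
  require_columns(df, c("token", "category", "action"), "comorbidity map")
  bad <- !df$action %in% c("include", "exclude")
  if (any(bad))
    stop(sprintf("comorbidity map: unknown action(s): %s",
                 paste(unique(df$action[bad]), collapse = ", ")),
         call. = FALSE)
  inc <- df[df$action == "include", , drop = FALSE]
  exc <- df[df$action == "exclude", , drop = FALSE]
  both <- intersect(inc$token, exc$token)
  if (length(both) > 0L)
    stop(sprintf("comorbidity map: token(s) both included and excluded: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  multi <- unique(inc$token[duplicated(paste(inc$token)) &
                              !duplicated(paste(inc$token, inc$category))])
  # tokens listed twice with the same category are tolerated; two
  # different categories for one token are not
  cat_per_token <- tapply(inc$category, inc$token,
                          function(x) length(unique(x)))
  offenders <- names(cat_per_token)[cat_per_token > 1]
  if (length(offenders) > 0L)
    stop(sprintf("comorbidity map: token(s) mapped to multiple categories: %s",
                 paste(offenders, collapse = ", ")), call. = FALSE)
  inc <- inc[!duplicated(inc$token), , drop = FALSE]
  structure(list(categories = unique(df$category[df$action == "include"]),
                 mapping = stats::setNames(inc$category, inc$token),
                 exclusions = unique(exc$token)),
            class = "comorbidity_map")
}

#' @export
print.comorbidity_map <- function(x, ...) {
  cat(sprintf("comorbidity map: %d categories, %d tokens (%d excluded)\n",
              length(x$categories), length(x$mapping), length(x$exclusions)))
  invisible(x)
}

#' Count comorbidities from medication tokens
#'
#' Maps each person's medication tokens to comorbidity categories and
#' counts the distinct categories hit. Tokens on the exclusion list
#' contribute nothing; unknown tokens are ignored (reported once per
#' token via a message). When `index_condition_category` is supplied it
#' is removed from the count, so the count measures conditions *other*
#' than the trial's index condition; pass `NULL` to count all categories.
#'
#' @param medications a character vector of tokens (one person), or a
#'   list of such vectors (several persons).
#' @param map a `comorbidity_map` from [load_comorbidity_map()].
#' @param index_condition_category optional category name excluded from
#'   the count (default `NULL`).
#' @return integer vector of multimorbidity counts, one per person.
#' @export
count_comorbidities <- function(medications, map,
                                index_condition_category = NULL) {
  stopifnot(inherits(map, "comorbidity_map"))
  if (!is.list(medications)) medications <- list(medications)
  if (!is.null(index_condition_category) &&
      length(map$categories) > 0L &&
      !index_condition_category %in% map$categories)
    warning(sprintf("index condition category '%s' is not in the map",
                    index_condition_category))
  known <- c(names(map$mapping), map$exclusions)
  unknown <- setdiff(unique(unlist(medications)), known)
  if (length(unknown) > 0L)
    message(sprintf("ignoring %d unknown medication token(s): %s",
                    length(unknown),
                    paste(utils::head(unknown, 5L), collapse = ", ")))
  vapply(medications, function(tok) {
    tok <- setdiff(unique(tok), map$exclusions)
    cats <- unique(unname(map$mapping[intersect(tok, names(map$mapping))]))
    cats <- setdiff(cats, index_condition_category)
    length(cats)
  }, integer(1))
}

# token list splitter shared by the generator and the IPD readers:
# medications are serialized as ';'-separated strings in CSV columns.
split_medications <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}
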