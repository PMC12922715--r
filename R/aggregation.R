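# Mapping fine-grained class-probability vectors (e.g. 1000 ImageNet
# classes) to the 8 basic-level superclasses and producing decisions.

#' The eight basic-level superclasses
#'
#' Canonical label order used for decisions and tie-breaking.
#' @export
SUPERCLASSES <- c("airplane", "bear", "bicycle", "bird",
                  "boat", "car", "dog", "elephant")

#' Animal superclasses (for the binary animal-detection collapse)
#' @export
ANIMAL_CLASSES <- c("bear", "bird", "dog", "elephant")

#' Read a fine-to-superclass mapping file
#'
#' Two-column delimited text (tab or whitespace) with header columns
#' `fine_class_id` and `superclass`.  The map may be partial (unmapped fine
#' classes are ignored during aggregation) but every superclass present must
#' map each fine class to exactly one superclass.
#'
#' @param path mapping file.
#' @return Data frame with columns `fine_class_id`, `superclass`.
#' @export
read_class_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("fine_class_id", "superclass")
  if (!all(required %in% names(map))) {
    stop("mapping file must have columns fine_class_id and superclass",
         call. = FALSE)
  }
  map$fine_class_id <- as.character(map$fine_class_id)
  if (anyDuplicated(map$fine_class_id)) {
    stop("each fine class may map to exactly one superclass", call. = FALSE)
  }
  bad <- setdiff(unique(map$superclass), SUPERCLASSES)
  if (length(bad)) {
    stop("unknown superclass label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map
}

#' Aggregate fine-class probabilities to superclass scores
#'
#' The score of each superclass is the *average* probability of its
#' constituent fine classes.  Averaging (rather than summing) is the correct
#' way to handle the shifted class prior at test time, so scores are not
#' renormalised before the argmax; renormalised scores are returned
#' alongside for reporting.
#'
#' @param probs numeric vector of fine-class probabilities, named by fine
#'   class id, nonnegative and summing to 1 within `1e-6`.
#' @param map data frame as returned by [read_class_map()], or a named
#'   character vector `fine_class_id -> superclass`.
#' @return Object of class `"ec_scores"`: list with `scores` (named length-8
#'   vector of mean constituent probabilities), `normalized` (scores divided
#'   by their sum), and `decision` (argmax under the fixed label order).
#' @export
aggregate_probabilities <- function(probs, map) {
  if (is.null(names(probs))) {
    stop("probs must be named by fine class id", call. = FALSE)
  }
  if (anyNA(probs) || any(probs < 0)) {
    stop("probabilities must be nonnegative", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-6) {
    stop("probabilities must sum to 1 (tolerance 1e-6); got ",
         format(sum(probs)), call. = FALSE)
  }
  if (is.data.frame(map)) {
    map <- stats::setNames(map$superclass, map$fine_class_id)
  }
  scores <- vapply(SUPERCLASSES, function(s) {
    members <- names(map)[map == s]
    members <- intersect(members, names(probs))
    if (length(members) == 0L) {
      stop("superclass '", s, "' has no constituent fine class in probs",
           call. = FALSE)
    }
    mean(probs[members])
  }, numeric(1))
  structure(list(scores = scores,
                 normalized = scores / sum(scores),
                 decision = decide_class(scores)),
            class = "ec_scores")
}

#' Decide the superclass from aggregated scores
#'
#' Argmax over the 8 superclass scores.  Exact ties are broken by the fixed
#' canonical label order ([SUPERCLASSES]) by default, or uniformly at random
#' (reproducibly, given `seed`).
#'
#' @param scores named numeric vector over the 8 superclasses (an
#'   `"ec_scores"` object is also accepted).
#' @param tie_rule `"fixed"` or `"random"`.
#' @param seed seed for the random tie rule.
#' @return A superclass label.
#' @export
decide_class <- function(scores, tie_rule = c("fixed", "random"), seed = NULL) {
  tie_rule <- match.arg(tie_rule)
  if (inherits(scores, "ec_scores")) scores <- scores$scores
  if (!all(SUPERCLASSES %in% names(scores)) || length(scores) != 8L) {
    stop("scores must be named with all 8 superclasses", call. = FALSE)
  }
  scores <- scores[SUPERCLASSES]  # canonical order governs ties
  top <- which(scores == max(scores))
  if (length(top) == 1L || tie_rule == "fixed") {
    return(names(scores)[top[1L]])
  }
  names(scores)[with_seed(seed, sample(top, 1L))]
}

#' Softmax over similarity scores
#'
#' Converts raw similarities (e.g. cosine similarities between image and
#' caption embeddings) into a probability vector via a numerically
#' stabilised softmax, `exp((x - max x)/T) / sum(...)`.
#'
#' @param similarities numeric vector, optionally named by class id.
#' @param temperature softmax temperature (> 0).
#' @return Probability vector of the same length and names, summing to 1.
#' @export
softmax_scores <- function(similarities, temperature = 1) {
  if (!all(is.finite(similarities))) {
    stop("similarities must be finite", call. = FALSE)
  }
  stopifnot(temperature > 0)
  z <- similarities / temperature
  e <- exp(z - max(z))
  e / sum(e)
}
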