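#' White-matter tract atlas used throughout the pipeline
#'
#' Returns the fixed probabilistic-tractography atlas of 15 major white
#' matter tracts (12 bilateral, 3 unilateral midline structures) that
#' together contribute 27 tract variables: each bilateral tract has a left
#' and a right measurement, each unilateral tract one. The tracts are
#' partitioned into three categories whose variable counts are 12
#' (association fibres), 6 (thalamic radiations) and 9 (projection fibres).
#' The forceps minor, forceps major and middle cerebellar peduncle are
#' midline structures and are treated as unilateral.
#'
#' @return A data.frame with one row per tract and columns
#'   \describe{
#'     \item{tract_id}{short identifier, e.g. \code{"slf"}}
#'     \item{name}{full tract name}
#'     \item{category}{one of \code{"association"}, \code{"thalamic"},
#'       \code{"projection"}}
#'     \item{bilateral}{logical; does the tract have left/right measures?}
#'   }
#' @examples
#' atlas <- make_tract_atlas()
#' nrow(atlas_variables(atlas))            # 27
#' table(atlas_variables(atlas)$category)  # 12 / 6 / 9
#' @export
make_tract_atlas <- function() {
  atlas <- data.frame(
    tract_id = c("ifof", "ilf", "slf", "unc", "cgc", "cgh",
                 "atr", "str", "ptr",
                 "ar", "cst", "ml", "fmi", "fma", "mcp"),
    name = c("Inferior fronto-occipital fasciculus",
             "Inferior longitudinal fasciculus",
             "Superior longitudinal fasciculus",
             "Uncinate fasciculus",
             "Cingulate gyrus part of cingulum",
             "Parahippocampal part of cingulum",
             "Anterior thalamic radiation",
             "Superior thalamic radiation",
             "Posterior thalamic radiation",
             "Acoustic radiation",
             "Corticospinal tract",
             "Medial lemniscus",
             "Forceps minor",
             "Forceps major",
             "Middle cerebellar peduncle"),
    category = c(rep("association", 6L),
                 rep("thalamic", 3L),
                 rep("projection", 6L)),
    bilateral = c(rep(TRUE, 12L), FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("tract_atlas", "data.frame")
  atlas
}

#' Enumerate the tract variables of an atlas
#'
#' Expands an atlas into its measurement variables: one row per
#' (tract, hemisphere) for bilateral tracts and one row with hemisphere
#' \code{"none"} for unilateral tracts. The full atlas yields 27 variables.
#'
#' @param atlas a \code{tract_atlas} from [make_tract_atlas()].
#' @param category optional category filter
#'   (\code{"association"}, \code{"thalamic"}, \code{"projection"}).
#' @return data.frame with columns \code{tract_id}, \code{hemisphere},
#'   \code{category}, \code{variable} (unique variable id such as
#'   \code{"slf_left"} or \code{"fmi"}).
#' @export
atlas_variables <- function(atlas, category = NULL) {
  stopifnot(inherits(atlas, "tract_atlas") || is.data.frame(atlas))
  if (!is.null(category)) {
    category <- match.arg(category, c("association", "thalamic", "projection"))
    atlas <- atlas[atlas$category == category, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(atlas)), function(i) {
    tr <- atlas[i, ]
    hemis <- if (tr$bilateral) c("left", "right") else "none"
    data.frame(tract_id = tr$tract_id,
               hemisphere = hemis,
               category = tr$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$variable <- ifelse(out$hemisphere == "none", out$tract_id,
                         paste(out$tract_id, out$hemisphere, sep = "_"))
  out
}
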