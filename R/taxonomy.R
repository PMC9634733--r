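# Label taxonomies: the detailed (26-class) and aggregated (13-class)
# constellations of intracranial artery segments, and the mapping between
# them. Index convention: background = 0, non-annotated = 1, artery classes
# follow in reading order with dexter (right) before sinister (left).

# base artery symbols in reading order; paired = has D-/S- laterality
.BASE_ARTERIES <- data.frame(
  code = c("ICA", "ICA-CoW", "M1", "M2-sup", "M2-inf", "A1", "ACOM",
           "A2", "VA", "BA", "PCOM", "P1", "P2"),
  description = c(
    "internal carotid artery",
    "internal carotid artery, Circle of Willis segment",
    "middle cerebral artery, first segment",
    "middle cerebral artery, second segment superior",
    "middle cerebral artery, second segment inferior",
    "anterior cerebral artery, first segment",
    "anterior communicating artery",
    "anterior cerebral artery, second segment",
    "vertebral artery",
    "basilar artery",
    "posterior communicating artery",
    "posterior cerebral artery, first segment",
    "posterior cerebral artery, second segment"),
  paired = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
             TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

.expand_laterality <- function(base) {
  rows <- list()
  for (i in seq_len(nrow(base))) {
    b <- base[i, ]
    if (b$paired) {
      rows[[length(rows) + 1L]] <- data.frame(
        code = paste0("D-", b$code),
        description = paste("right", b$description), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        code = paste0("S-", b$code),
        description = paste("left", b$description), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        code = b$code, description = b$description, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.new_taxonomy <- function(name, classes, aggregation_map = NULL) {
  stopifnot(identical(classes$index, seq_len(nrow(classes)) - 1L),
            !anyDuplicated(classes$code))
  structure(list(
    name = name,
    classes = classes,
    background_index = 0L,
    nonannotated_index = 1L,
    aggregation_map = aggregation_map
  ), class = "label_taxonomy")
}

.aux_classes <- data.frame(
  index = 0:1, code = c("BG", "NA-VESSEL"),
  description = c("background", "non-annotated vessel"),
  stringsAsFactors = FALSE)

#' Detailed 26-class artery taxonomy
#'
#' Builds the detailed label constellation: 24 named artery segment classes
#' (13 base arteries, paired ones duplicated into dexter `D-` and sinister
#' `S-` variants; the anterior communicating artery and the basilar artery
#' are unpaired), plus background (index 0) and non-annotated vessel
#' (index 1).
#'
#' @return A `label_taxonomy` object with 26 classes and the mapping onto
#'   the aggregated constellation (see [aggregated_taxonomy()]).
#' @seealso [aggregated_taxonomy()], [aggregate_labels()]
#' @export
#' @examples
#' tax <- detailed_taxonomy()
#' nrow(tax$classes)  # 26
detailed_taxonomy <- function() {
  art <- .expand_laterality(.BASE_ARTERIES)
  classes <- rbind(
    .aux_classes,
    data.frame(index = seq_len(nrow(art)) + 1L, code = art$code,
               description = art$description, stringsAsFactors = FALSE))
  rownames(classes) <- NULL
  .new_taxonomy("detailed", classes, aggregation_map = .aggregation_map())
}

# aggregated groups in reading order; each entry: group code -> detailed codes
.AGG_GROUPS <- list(
  "D-ICA-grp" = c("D-ICA", "D-ICA-CoW"),
  "S-ICA-grp" = c("S-ICA", "S-ICA-CoW"),
  "D-MCA"     = c("D-M1", "D-M2-sup", "D-M2-inf"),
  "S-MCA"     = c("S-M1", "S-M2-sup", "S-M2-inf"),
  "D-ACA"     = c("D-A1", "D-A2"),
  "S-ACA"     = c("S-A1", "S-A2", "ACOM"),
  "BA-grp"    = "BA",
  "D-VA-grp"  = "D-VA",
  "S-VA-grp"  = "S-VA",
  "D-PCA"     = c("D-PCOM", "D-P1", "D-P2"),
  "S-PCA"     = c("S-PCOM", "S-P1", "S-P2")
)

.AGG_DESCRIPTIONS <- c(
  "right internal carotid artery (ICA + ICA CoW)",
  "left internal carotid artery (ICA + ICA CoW)",
  "right middle cerebral artery (M1 + M2 sup + M2 inf)",
  "left middle cerebral artery (M1 + M2 sup + M2 inf)",
  "right anterior cerebral artery (A1 + A2)",
  "left anterior cerebral artery (A1 + A2 + AcomA)",
  "basilar artery",
  "right vertebral artery",
  "left vertebral artery",
  "right posterior circulation (PcomA + P1 + P2)",
  "left posterior circulation (PcomA + P1 + P2)")

#' Aggregated 13-class artery taxonomy
#'
#' Builds the clinically grouped label constellation: 11 artery groups
#' (left/right ICA incl. its Circle-of-Willis segment, left/right MCA,
#' right ACA, left ACA incl. the anterior communicating artery, basilar
#' artery, left/right vertebral artery, left/right posterior circulation)
#' plus background and non-annotated vessel.
#'
#' @return A `label_taxonomy` object with 13 classes.
#' @export
aggregated_taxonomy <- function() {
  classes <- rbind(
    .aux_classes,
    data.frame(index = seq_along(.AGG_GROUPS) + 1L,
               code = names(.AGG_GROUPS),
               description = .AGG_DESCRIPTIONS, stringsAsFactors = FALSE))
  rownames(classes) <- NULL
  .new_taxonomy("aggregated", classes)
}

# detailed index -> aggregated index, total over all 26 detailed classes
.aggregation_map <- function() {
  art <- .expand_laterality(.BASE_ARTERIES)
  det_codes <- c("BG", "NA-VESSEL", art$code)
  agg <- aggregated_taxonomy()
  map <- integer(length(det_codes))
  names(map) <- det_codes
  map["BG"] <- 0L
  map["NA-VESSEL"] <- 1L
  for (g in names(.AGG_GROUPS)) {
    gi <- agg$classes$index[agg$classes$code == g]
    map[.AGG_GROUPS[[g]]] <- gi
  }
  map
}

#' Map a detailed label volume onto the aggregated constellation
#'
#' Applies the detailed-to-aggregated class mapping voxel-wise. Background
#' and non-annotated voxels are preserved; each artery class is replaced by
#' the index of its clinical group. Shape and spacing are preserved.
#'
#' @param labels integer array (or `volume_grid`) of detailed class indices.
#' @param taxonomy a detailed `label_taxonomy`; defaults to
#'   [detailed_taxonomy()].
#' @return label volume of the same shape on aggregated indices.
#' @export
aggregate_labels <- function(labels, taxonomy = detailed_taxonomy()) {
  if (is.null(taxonomy$aggregation_map))
    stop("taxonomy has no aggregation map (is it the detailed taxonomy?)")
  map <- taxonomy$aggregation_map
  vals <- as.integer(labels)
  bad <- vals < 0L | vals >= length(map)
  bad[is.na(vals)] <- TRUE
  if (any(bad)) {
    off <- unique(vals[bad])
    stop("unknown detailed label index: ", paste(off, collapse = ", "))
  }
  out <- map[vals + 1L]
  attributes(out) <- attributes(labels)
  storage.mode(out) <- "integer"
  out
}

#' @export
print.label_taxonomy <- function(x, ...) {
  cat(sprintf("label_taxonomy '%s': %d classes (%d artery + 2 auxiliary)\n",
              x$name, nrow(x$classes), nrow(x$classes) - 2L))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Serialize a taxonomy to JSON
#'
#' @param taxonomy a `label_taxonomy`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
taxonomy_to_json <- function(taxonomy, path = NULL) {
  obj <- list(name = taxonomy$name,
              classes = taxonomy$classes,
              background_index = taxonomy$background_index,
              nonannotated_index = taxonomy$nonannotated_index)
  if (!is.null(taxonomy$aggregation_map))
    obj$aggregation_map <- as.list(taxonomy$aggregation_map)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
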