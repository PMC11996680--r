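# Data model and CSV input/output for traced kymograph tracks.
#
# A track is the ordered set of vertices of a multisegmented line traced over
# one motor complex in a kymograph. Tracks are stored in long form, one row
# per vertex, with positions in nanometers along the microtubule axis
# (positive toward the plus end once oriented) and times in seconds from the
# movie start. Contexts carry the per-kymograph geometry needed for rates.

POLARITY_LEVELS <- c("plus_right", "plus_left", "unknown")

#' Validate a kymograph context table
#'
#' A context describes one kymograph (one microtubule in one movie): its
#' length, the movie duration, the pixel size and frame interval of the
#' acquisition, and the polarity orientation of the spatial axis.
#'
#' @param contexts Data frame with columns `context_id`, `mt_length_nm`,
#'   `duration_s`, `pixel_size_nm`, `frame_interval_s`, `polarity`
#'   (one of `"plus_right"`, `"plus_left"`, `"unknown"`).
#' @return The validated data frame (invisibly classed `kymo_contexts`).
#' @export
validate_contexts <- function(contexts) {
  req <- c("context_id", "mt_length_nm", "duration_s", "pixel_size_nm",
           "frame_interval_s", "polarity")
  miss <- setdiff(req, names(contexts))
  if (length(miss) > 0)
    stop("context table is missing columns: ", paste(miss, collapse = ", "))
  contexts$context_id <- as.character(contexts$context_id)
  if (anyDuplicated(contexts$context_id))
    stop("duplicate context_id in context table: ",
         paste(unique(contexts$context_id[duplicated(contexts$context_id)]),
               collapse = ", "))
  for (col in c("mt_length_nm", "duration_s", "pixel_size_nm", "frame_interval_s")) {
    v <- contexts[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("context column '", col, "' must be finite and > 0")
  }
  bad <- !contexts$polarity %in% POLARITY_LEVELS
  if (any(bad))
    stop("unknown polarity value(s): ",
         paste(unique(contexts$polarity[bad]), collapse = ", "))
  class(contexts) <- union("kymo_contexts", class(contexts))
  invisible(contexts)
}

#' Validate a track vertex table
#'
#' Checks the long-form vertex table against the track invariants: every
#' track has at least two vertices, strictly increasing non-negative times,
#' finite positions, and a context defined in `contexts`.
#'
#' @param vertices Data frame with columns `track_id`, `context_id`, `t_s`,
#'   `x_nm`, ordered within track.
#' @param contexts Validated context table (see [validate_contexts()]).
#' @return The vertex table, with ids coerced to character, invisibly.
#' @export
validate_tracks <- function(vertices, contexts) {
  req <- c("track_id", "context_id", "t_s", "x_nm")
  miss <- setdiff(req, names(vertices))
  if (length(miss) > 0)
    stop("track table is missing columns: ", paste(miss, collapse = ", "))
  vertices$track_id <- as.character(vertices$track_id)
  vertices$context_id <- as.character(vertices$context_id)
  if (nrow(vertices) == 0) return(invisible(vertices))
  if (!is.numeric(vertices$t_s) || !is.numeric(vertices$x_nm))
    stop("t_s and x_nm must be numeric")
  if (any(!is.finite(vertices$t_s)) || any(!is.finite(vertices$x_nm)))
    stop("non-finite vertex coordinates")
  if (any(vertices$t_s < 0))
    stop("negative vertex times")
  contexts <- validate_contexts(as.data.frame(contexts))
  undef <- setdiff(unique(vertices$context_id), contexts$context_id)
  if (length(undef) > 0)
    stop("track table references undefined context(s): ",
         paste(undef, collapse = ", "))
  for (id in unique(vertices$track_id)) {
    sub <- vertices[vertices$track_id == id, ]
    if (nrow(sub) < 2)
      stop("track '", id, "' has fewer than 2 vertices")
    if (length(unique(sub$context_id)) > 1)
      stop("track '", id, "' spans more than one context")
    if (any(diff(sub$t_s) <= 0))
      stop("track '", id, "' has non-monotone vertex times")
  }
  invisible(vertices)
}

#' Read a traced-track table from CSV
#'
#' @param path CSV file with columns `track_id`, `context_id`, `t_s`, `x_nm`.
#' @param contexts Context table against which tracks are validated.
#' @return Validated vertex data frame.
#' @export
read_tracks <- function(path, contexts) {
  if (!file.exists(path)) stop("track file not found: ", path)
  vertices <- utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = c(track_id = "character",
                                             context_id = "character"))
  validate_tracks(vertices, contexts)
  vertices
}

#' Write a traced-track table to CSV at full double precision
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces every vertex bit-identically.
#'
#' @param vertices Vertex data frame (may be empty; the header is written
#'   regardless).
#' @param path Output CSV path.
#' @export
write_tracks <- function(vertices, path) {
  out <- data.frame(
    track_id = as.character(vertices$track_id),
    context_id = as.character(vertices$context_id),
    t_s = sprintf("%.17g", vertices$t_s),
    x_nm = sprintf("%.17g", vertices$x_nm),
    stringsAsFactors = FALSE
  )
  if (nrow(vertices) == 0)
    out <- data.frame(track_id = character(), context_id = character(),
                      t_s = character(), x_nm = character())
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kymograph context table from CSV
#' @param path CSV file; see [validate_contexts()] for columns.
#' @return Validated context data frame.
#' @export
read_contexts <- function(path) {
  if (!file.exists(path)) stop("context file not found: ", path)
  ctx <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(context_id = "character"))
  validate_contexts(ctx)
  ctx
}

#' Write a kymograph context table to CSV
#' @param contexts Context data frame.
#' @param path Output path.
#' @export
write_contexts <- function(contexts, path) {
  utils::write.csv(as.data.frame(contexts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an experiment manifest
#'
#' The manifest maps each kymograph context into the replicate hierarchy:
#' condition > experiment > movie > microtubule (context). Every context
#' belongs to exactly one condition/experiment/movie.
#'
#' @param manifest Data frame with columns `condition`, `experiment_id`,
#'   `movie_id`, `context_id`.
#' @param contexts Optional context table; if given, every manifest context
#'   must exist and every context must be listed.
#' @return The manifest, ids as character, invisibly.
#' @export
validate_manifest <- function(manifest, contexts = NULL) {
  req <- c("condition", "experiment_id", "movie_id", "context_id")
  miss <- setdiff(req, names(manifest))
  if (length(miss) > 0)
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  for (col in req) manifest[[col]] <- as.character(manifest[[col]])
  if (anyDuplicated(manifest$context_id))
    stop("manifest lists context_id more than once: ",
         paste(unique(manifest$context_id[duplicated(manifest$context_id)]),
               collapse = ", "))
  if (!is.null(contexts)) {
    undef <- setdiff(manifest$context_id, as.character(contexts$context_id))
    if (length(undef) > 0)
      stop("manifest references undefined context(s): ",
           paste(undef, collapse = ", "))
  }
  invisible(manifest)
}

#' Read an experiment manifest from CSV
#' @param path CSV path.
#' @param contexts Optional context table for cross-validation.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path, contexts = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_manifest(man, contexts)
  man
}

#' Orient tracks to the plus-end-positive convention
#'
#' Every downstream threshold assumes x increases toward the microtubule
#' plus end. Kymographs traced with the plus end to the left have their
#' positions negated; `plus_right` tracks pass through unchanged. Polarity
#' is established experimentally (e.g. by a kinesin-only polarity check) and
#' must be recorded in the context table before analysis.
#'
#' @param vertices Vertex table.
#' @param contexts Context table with a `polarity` column.
#' @return Vertex table with all `x_nm` in plus-end-positive coordinates.
#' @export
orient_tracks <- function(vertices, contexts) {
  contexts <- as.data.frame(contexts)
  pol <- contexts$polarity[match(vertices$context_id, contexts$context_id)]
  if (anyNA(pol))
    stop("track table references undefined context(s): ",
         paste(unique(vertices$context_id[is.na(pol)]), collapse = ", "))
  if (any(pol == "unknown")) {
    bad <- unique(vertices$context_id[pol == "unknown"])
    stop("polarity is 'unknown' for context(s) ",
         paste(bad, collapse = ", "),
         "; record the microtubule orientation (polarity check) before analysis")
  }
  flip <- pol == "plus_left"
  vertices$x_nm[flip] <- -vertices$x_nm[flip]
  vertices
}

#' Orient a single track
#'
#' @param t_s,x_nm Vertex times and positions of one track.
#' @param polarity `"plus_right"`, `"plus_left"` or `"unknown"`.
#' @return Numeric vector of oriented positions.
#' @export
orient_track <- function(t_s, x_nm, polarity) {
  if (identical(polarity, "unknown"))
    stop("polarity is 'unknown'; record the microtubule orientation ",
         "(polarity check) before analysis")
  if (!polarity %in% POLARITY_LEVELS)
    stop("unknown polarity value: ", polarity)
  if (polarity == "plus_left") -x_nm else x_nm
}

# Split a vertex table into a named list of per-track data frames,
# preserving first-appearance order.
split_tracks <- function(vertices) {
  ids <- unique(vertices$track_id)
  out <- split(vertices, factor(vertices$track_id, levels = ids))
  out
}
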