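#' Binary feature vector
#'
#' Perceptual attributes are encoded as binary feature vectors of a fixed,
#' scenario-wide dimensionality. Each element indicates the presence of one
#' elementary feature; the memory network has one node per feature.
#'
#' @param bits Numeric or integer vector of 0/1 values.
#' @return An integer vector of class `feature_vector`.
#' @export
feature_vector <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) == 0L || anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("feature vector must be a nonempty binary (0/1) vector", call. = FALSE)
  }
  structure(bits, class = "feature_vector")
}

#' Object attribute
#'
#' An attribute is one perceivable property of an object (shape, colour,
#' price tag, ...). When attended it emits its feature vector as input to
#' the memory network.
#'
#' @param id Character scalar, unique within the owning object.
#' @param features A [feature_vector()] (or plain 0/1 vector).
#' @return A list of class `attribute`.
#' @export
attribute <- function(id, features) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!inherits(features, "feature_vector")) features <- feature_vector(features)
  structure(list(id = id, features = features), class = "attribute")
}

#' Scene object
#'
#' An object sits at a spatial location (0-based index) and owns one or more
#' attributes. Salience is the bottom-up attention input for that location;
#' the simulations use binary salience (0 = absent, 1 = present) but any
#' nonnegative value is accepted.
#'
#' @param id Character scalar.
#' @param location Integer location index, >= 0, unique within a scene.
#' @param attributes Nonempty list of [attribute()] objects.
#' @param salience Nonnegative number, default 1.
#' @return A list of class `scene_object`.
#' @export
scene_object <- function(id, location, attributes, salience = 1) {
  stopifnot(is.character(id), length(id) == 1L)
  location <- as.integer(location)
  if (is.na(location) || location < 0L) {
    stop("location must be an integer >= 0", call. = FALSE)
  }
  if (inherits(attributes, "attribute")) attributes <- list(attributes)
  if (length(attributes) < 1L) {
    stop("scene object '", id, "' needs at least one attribute", call. = FALSE)
  }
  if (!all(vapply(attributes, inherits, logical(1), "attribute"))) {
    stop("attributes must be a list of attribute objects", call. = FALSE)
  }
  ids <- vapply(attributes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("attribute ids must be unique within an object", call. = FALSE)
  }
  if (!is.numeric(salience) || length(salience) != 1L || salience < 0) {
    stop("salience must be a single nonnegative number", call. = FALSE)
  }
  structure(list(id = id, location = location, attributes = attributes,
                 salience = as.numeric(salience)),
            class = "scene_object")
}

#' Scene
#'
#' The stimulus world: a set of objects at distinct locations, all sharing
#' the same feature dimensionality.
#'
#' @param objects List of [scene_object()]s.
#' @param feature_dim Feature-vector length common to every attribute.
#' @return A list of class `scene`.
#' @export
scene <- function(objects, feature_dim) {
  if (inherits(objects, "scene_object")) objects <- list(objects)
  if (length(objects) < 1L) stop("a scene needs at least one object", call. = FALSE)
  if (!all(vapply(objects, inherits, logical(1), "scene_object"))) {
    stop("objects must be a list of scene_object", call. = FALSE)
  }
  feature_dim <- as.integer(feature_dim)
  locs <- vapply(objects, `[[`, integer(1), "location")
  if (anyDuplicated(locs)) stop("object locations must be unique", call. = FALSE)
  for (ob in objects) {
    for (at in ob$attributes) {
      if (length(at$features) != feature_dim) {
        stop("attribute '", at$id, "' of object '", ob$id,
             "' has feature length ", length(at$features),
             ", expected ", feature_dim, call. = FALSE)
      }
    }
  }
  structure(list(objects = objects, feature_dim = feature_dim), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> ", length(x$objects), " object(s), feature_dim = ",
      x$feature_dim, "\n", sep = "")
  for (ob in x$objects) {
    cat("  [", ob$location, "] ", ob$id, ": ",
        length(ob$attributes), " attribute(s), salience ", ob$salience,
        "\n", sep = "")
  }
  invisible(x)
}

#' Sample one attribute of an object uniformly at random
#'
#' Perceptual scanning processes one attribute at a time; while attention
#' dwells on an object its attributes are re-drawn uniformly at random.
#' Uses the current R random stream, so results are reproducible under
#' [set.seed()].
#'
#' @param object A [scene_object()].
#' @return One [attribute()].
#' @export
sample_attribute <- function(object) {
  stopifnot(inherits(object, "scene_object"))
  k <- length(object$attributes)
  if (k < 1L) stop("object has no attributes", call. = FALSE)
  # floor(u*k) rather than sample(): identical draw order in the compiled engine
  idx <- floor(stats::runif(1) * k) + 1L
  if (idx > k) idx <- k
  object$attributes[[idx]]
}

#' Salience vector of a scene
#'
#' One entry per location from 0 up to the highest occupied location;
#' empty locations get salience 0.
#'
#' @param scn A [scene()].
#' @return Numeric vector; element `i` is the salience at location `i - 1`.
#' @export
salience_vector <- function(scn) {
  stopifnot(inherits(scn, "scene"))
  locs <- vapply(scn$objects, `[[`, integer(1), "location")
  out <- numeric(max(locs) + 1L)
  for (ob in scn$objects) out[ob$location + 1L] <- ob$salience
  out
}
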