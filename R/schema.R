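# Clinical metadata schema and featurization.
#
# Raw records hold one value per clinical attribute; NA is the missing marker.
# Encoding follows the all-zero missing convention: numerics are kept as-is
# (optionally standardized on a training fold), booleans map to 0/1, and
# categoricals are one-hot encoded with an all-zero block for missing values.

#' Describe one clinical metadata attribute
#'
#' @param name Attribute name (unique within a schema).
#' @param kind One of `"numeric"`, `"boolean"`, `"categorical"`.
#' @param categories For categorical attributes, the ordered category
#'   vocabulary (at least two unique values); must be empty otherwise.
#' @param unit Measurement unit, e.g. `"years"` or `"mm"` (informational).
#' @return An object of class `attribute_spec`.
#' @export
attribute_spec <- function(name, kind = c("numeric", "boolean", "categorical"),
                           categories = character(), unit = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (kind == "categorical") {
    if (length(categories) < 2L) {
      stop("categorical attribute '", name, "' needs >= 2 categories")
    }
    if (anyDuplicated(categories)) {
      stop("categorical attribute '", name, "' has duplicate categories")
    }
  } else if (length(categories)) {
    stop("non-categorical attribute '", name, "' must not declare categories")
  }
  structure(list(name = name, kind = kind, categories = categories, unit = unit),
            class = "attribute_spec")
}

# Encoded width contributed by one attribute.
attr_width <- function(spec) {
  if (spec$kind == "categorical") length(spec$categories) else 1L
}

#' Build a metadata schema from attribute specs
#'
#' @param attributes List of [attribute_spec()] objects with unique names.
#' @return An object of class `meta_schema` with fields `attributes` and
#'   `width` (total encoded vector length).
#' @export
meta_schema <- function(attributes) {
  stopifnot(length(attributes) >= 1L)
  nm <- vapply(attributes, function(a) a$name, character(1))
  if (anyDuplicated(nm)) stop("attribute names must be unique")
  width <- sum(vapply(attributes, attr_width, integer(1)))
  structure(list(attributes = attributes, width = as.integer(width)),
            class = "meta_schema")
}

#' @export
print.meta_schema <- function(x, ...) {
  cat("Clinical metadata schema:", length(x$attributes), "attributes,",
      "encoded width", x$width, "\n")
  for (a in x$attributes) {
    extra <- if (a$kind == "categorical") {
      paste0(" {", paste(a$categories, collapse = ", "), "}")
    } else if (nzchar(a$unit)) paste0(" [", a$unit, "]") else ""
    cat(sprintf("  %-20s %-11s%s\n", a$name, a$kind, extra))
  }
  invisible(x)
}

# Default category vocabularies for the open-ended attributes. Gender order is
# pinned (male first, so male encodes as [1,0]); the rest are lexicographic.
# All are overridable at schema build time to track a given dataset release.
default_category_sets <- function() {
  countries <- sort(c("AUSTRIA", "BRAZIL", "CZECH", "GERMANY", "ITALY",
                      "NETHERLANDS", "POLAND", "POMERANIA", "PORTUGAL", "SPAIN"))
  list(
    gender = c("male", "female"),
    fitzpatrick = as.character(1:6),
    region = sort(c("ABDOMEN", "ARM", "BACK", "CHEST", "EAR", "FACE", "FOOT",
                    "FOREARM", "HAND", "LIP", "NECK", "NOSE", "SCALP", "THIGH")),
    father_country = countries,
    mother_country = countries
  )
}

#' Build the default 21-attribute clinical metadata schema
#'
#' The schema covers the clinical attributes recorded alongside smartphone
#' lesion photographs in the PAD-UFES-20 layout: three numeric attributes
#' (age in years, two lesion diameters in mm), thirteen boolean attributes
#' (patient history, household exposure and lesion symptoms) and five
#' categorical attributes (gender, Fitzpatrick skin phototype, body region
#' and the parents' countries of origin).
#'
#' @param categories Optional named list overriding the category vocabulary
#'   of any categorical attribute (e.g. to freeze the exact value sets
#'   observed in a dataset release).
#' @return A [meta_schema()] with exactly 21 attributes.
#' @export
build_default_schema <- function(categories = list()) {
  cats <- utils::modifyList(default_category_sets(), categories)
  a <- function(...) attribute_spec(...)
  meta_schema(list(
    a("smoking", "boolean"),
    a("drinking", "boolean"),
    a("father_country", "categorical", cats$father_country),
    a("mother_country", "categorical", cats$mother_country),
    a("age", "numeric", unit = "years"),
    a("gender", "categorical", cats$gender),
    a("cancer_history", "boolean"),
    a("skin_cancer_history", "boolean"),
    a("pesticide", "boolean"),
    a("sewage_system", "boolean"),
    a("piped_water", "boolean"),
    a("fitzpatrick", "categorical", cats$fitzpatrick),
    a("region", "categorical", cats$region),
    a("diameter_1", "numeric", unit = "mm"),
    a("diameter_2", "numeric", unit = "mm"),
    a("itch", "boolean"),
    a("grew", "boolean"),
    a("hurt", "boolean"),
    a("changed", "boolean"),
    a("bleed", "boolean"),
    a("elevation", "boolean")
  ))
}

schema_attr_names <- function(schema) {
  vapply(schema$attributes, function(a) a$name, character(1))
}

#' Feature names of the encoded vector
#'
#' One name per encoded slot: the attribute name for numeric/boolean slots,
#' `name=category` for each one-hot slot.
#'
#' @param schema A [meta_schema()].
#' @return Character vector of length `schema$width`.
#' @export
feature_names <- function(schema) {
  unlist(lapply(schema$attributes, function(a) {
    if (a$kind == "categorical") paste0(a$name, "=", a$categories) else a$name
  }), use.names = FALSE)
}

check_record <- function(schema, record) {
  nm <- schema_attr_names(schema)
  extra <- setdiff(names(record), nm)
  if (length(extra)) {
    stop("record has attributes not in schema: ", paste(extra, collapse = ", "))
  }
  invisible(record)
}

#' Fit per-attribute normalization statistics on training records
#'
#' Computes the center (mean) and scale (population standard deviation) of
#' every numeric attribute over the non-missing values of a set of training
#' records. A constant or fully-missing attribute falls back to scale 1 (and
#' center 0 when fully missing), with a warning for the fully-missing case.
#'
#' @param schema A [meta_schema()].
#' @param records Non-empty list of records (named lists; NA marks missing).
#' @return An object of class `normalizer_stats`: named list with `center`
#'   and `scale` vectors over the numeric attributes.
#' @export
fit_normalizer <- function(schema, records) {
  if (!length(records)) stop("records must be non-empty")
  num <- Filter(function(a) a$kind == "numeric", schema$attributes)
  nm <- vapply(num, function(a) a$name, character(1))
  center <- stats::setNames(numeric(length(nm)), nm)
  scale <- stats::setNames(rep(1, length(nm)), nm)
  for (name in nm) {
    v <- vapply(records, function(r) {
      x <- r[[name]]
      if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("attribute '", name, "': all values missing; using center 0, scale 1")
      next
    }
    center[name] <- mean(v)
    s <- sqrt(mean((v - mean(v))^2)) # population SD
    scale[name] <- if (s > 0) s else 1
  }
  structure(list(center = center, scale = scale), class = "normalizer_stats")
}

#' Encode one clinical record as a dense numeric vector
#'
#' Numeric slots carry the raw value (or the standardized value when `stats`
#' is supplied); boolean slots are 0/1; a categorical value sets exactly one
#' 1 in its one-hot block. Missing values (NA or absent key) encode as 0 in
#' numeric/boolean slots and as an all-zero one-hot block, so e.g. gender
#' male is `[1, 0]`, female `[0, 1]` and missing `[0, 0]`.
#'
#' @param schema A [meta_schema()].
#' @param record Named list of raw values; keys must be schema attributes.
#' @param stats Optional [fit_normalizer()] output; when given, numeric
#'   values are centered and scaled (missing numerics still encode as 0,
#'   i.e. the training mean).
#' @return Named numeric vector of length `schema$width`.
#' @export
encode_record <- function(schema, record, stats = NULL) {
  check_record(schema, record)
  out <- numeric(schema$width)
  pos <- 1L
  for (a in schema$attributes) {
    w <- attr_width(a)
    v <- record[[a$name]]
    missing_v <- is.null(v) || (length(v) == 1L && is.na(v))
    if (!missing_v) {
      if (a$kind == "numeric") {
        if (!is.numeric(v)) stop("attribute '", a$name, "': expected numeric, got ", class(v)[1])
        x <- as.numeric(v)
        if (!is.null(stats)) {
          x <- (x - stats$center[[a$name]]) / stats$scale[[a$name]]
        }
        out[pos] <- x
      } else if (a$kind == "boolean") {
        if (!is.logical(v) && !(is.numeric(v) && v %in% c(0, 1))) {
          stop("attribute '", a$name, "': expected logical, got ", class(v)[1])
        }
        out[pos] <- as.numeric(as.logical(v))
      } else {
        v <- as.character(v)
        j <- match(v, a$categories)
        if (is.na(j)) {
          stop("attribute '", a$name, "': value '", v,
               "' is not in the schema's category list")
        }
        out[pos + j - 1L] <- 1
      }
    }
    pos <- pos + w
  }
  names(out) <- feature_names(schema)
  out
}

#' Encode a list of records as a feature matrix
#'
#' @inheritParams encode_record
#' @param records List of records (possibly empty).
#' @return Numeric matrix with one row per record and `schema$width` columns
#'   named by [feature_names()].
#' @export
encode_table <- function(schema, records, stats = NULL) {
  m <- matrix(0, nrow = length(records), ncol = schema$width,
              dimnames = list(NULL, feature_names(schema)))
  for (i in seq_along(records)) m[i, ] <- encode_record(schema, records[[i]], stats)
  m
}

#' Write / read a frozen schema as YAML
#'
#' Freezing the schema to a file pins attribute order and category
#' vocabularies so featurization cannot drift between training and inference.
#'
#' @param schema A [meta_schema()].
#' @param path File path.
#' @return `read_schema` returns a [meta_schema()]; `write_schema` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  doc <- lapply(schema$attributes, function(a) {
    list(name = a$name, kind = a$kind,
         categories = as.list(a$categories), unit = a$unit)
  })
  yaml::write_yaml(list(attributes = doc), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  meta_schema(lapply(doc$attributes, function(a) {
    attribute_spec(a$name, a$kind, unlist(a$categories) %||% character(),
                   a$unit %||% "")
  }))
}
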