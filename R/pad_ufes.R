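# Reading and writing datasets in the PAD-UFES-20 on-disk dialect: an image
# folder plus one comma-separated metadata table with a header row, one row
# per lesion image, a `diagnostic` label column and the clinical attribute
# columns. Synthetic exports and the deposited dataset are interchangeable
# inputs to the harness.

# schema attribute name -> CSV column name
pad_column_map <- c(
  smoking = "smoke", drinking = "drink",
  father_country = "background_father", mother_country = "background_mother",
  age = "age", gender = "gender",
  cancer_history = "cancer_history",
  skin_cancer_history = "skin_cancer_history",
  pesticide = "pesticide", sewage_system = "has_sewage_system",
  piped_water = "has_piped_water", fitzpatrick = "fitspatrick",
  region = "region", diameter_1 = "diameter_1", diameter_2 = "diameter_2",
  itch = "itch", grew = "grew", hurt = "hurt", changed = "changed",
  bleed = "bleed", elevation = "elevation"
)

MISSING_TOKEN <- "UNK"

format_pad_value <- function(value, kind) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(MISSING_TOKEN)
  switch(kind,
         boolean = if (as.logical(value)) "True" else "False",
         numeric = format(as.numeric(value), scientific = FALSE),
         categorical = toupper(as.character(value)))
}

parse_pad_value <- function(raw, kind, attr_name) {
  if (is.na(raw) || raw %in% c(MISSING_TOKEN, "", "NA", "nan")) return(NA)
  switch(kind,
         boolean = tolower(raw) %in% c("true", "1"),
         numeric = as.numeric(raw),
         categorical = {
           v <- as.character(raw)
           if (attr_name == "gender") tolower(v)
           else if (attr_name == "fitzpatrick") {
             as.character(as.integer(round(as.numeric(v))))
           } else toupper(v)
         })
}

#' Export a dataset in the PAD-UFES-20 layout
#'
#' Writes `metadata.csv` (PAD column dialect: identifier columns, the 21
#' clinical attribute columns, the `diagnostic` label; booleans as
#' True/False, missing values as UNK) and, optionally, one PNG per image
#' under `images/`.
#'
#' @param dataset A [generate_dataset()] result (or any dataset list with
#'   `records`, `labels`, `ids` and optionally `images`).
#' @param dir Output directory (created if needed).
#' @param with_images Also write the PNG files.
#' @param schema The [meta_schema()] describing the records.
#' @return `dir`, invisibly.
#' @export
export_pad_ufes <- function(dataset, dir, with_images = TRUE,
                            schema = build_default_schema()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$records)
  cols <- list(patient_id = dataset$ids$patient_id,
               lesion_id = dataset$ids$lesion_id)
  for (a in schema$attributes) {
    cols[[pad_column_map[[a$name]]]] <- vapply(dataset$records, function(r) {
      format_pad_value(r[[a$name]], a$kind)
    }, character(1))
  }
  cols$diagnostic <- as.character(dataset$labels)
  cols$img_id <- dataset$ids$img_id
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "metadata.csv"), row.names = FALSE,
                   quote = TRUE)
  if (with_images && !is.null(dataset$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_len(n)) {
      png::writePNG(dataset$images[[i]],
                    file.path(img_dir, dataset$ids$img_id[i]))
    }
  }
  invisible(dir)
}

#' Read a dataset in the PAD-UFES-20 layout
#'
#' Accepts either a directory containing `metadata.csv` (plus an `images/`
#' folder) or a path to the metadata CSV itself. Boolean columns accept
#' True/False (any case); `UNK`, empty and `NA` entries become missing;
#' gender is lower-cased and the Fitzpatrick type is normalized to the
#' integer categories `"1"`..`"6"`.
#'
#' @param path Directory or metadata CSV path.
#' @param schema Target [meta_schema()].
#' @param load_images Read the PNG files referenced by `img_id` (requires
#'   the directory form).
#' @return Dataset list with `records`, `labels` (factor over
#'   [lesion_classes()]), `ids`, and `images` (NULL unless loaded).
#' @export
read_pad_ufes <- function(path, schema = build_default_schema(),
                          load_images = FALSE) {
  csv <- if (dir.exists(path)) file.path(path, "metadata.csv") else path
  if (!file.exists(csv)) stop("metadata CSV not found: ", csv)
  df <- utils::read.csv(csv, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"diagnostic" %in% names(df)) stop("CSV lacks the diagnostic column")
  n <- nrow(df)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- list()
    for (a in schema$attributes) {
      col <- pad_column_map[[a$name]]
      if (col %in% names(df)) {
        rec[[a$name]] <- parse_pad_value(df[[col]][i], a$kind, a$name)
      }
    }
    records[[i]] <- rec
  }
  labels <- as_lesion_factor(df$diagnostic)
  ids <- data.frame(
    patient_id = df$patient_id %||% rep(NA_character_, n),
    lesion_id = df$lesion_id %||% rep(NA_character_, n),
    img_id = df$img_id %||% rep(NA_character_, n)
  )
  images <- NULL
  if (load_images) {
    if (!dir.exists(path)) stop("load_images requires the directory form")
    images <- lapply(ids$img_id, function(f) {
      img <- png::readPNG(file.path(path, "images", f))
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
      img[, , 1:3, drop = FALSE]
    })
  }
  list(images = images, records = records, labels = labels, ids = ids)
}
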