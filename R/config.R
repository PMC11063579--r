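#' Study configuration
#'
#' A study configuration drives every other part of the registry: how
#' pseudonyms are formatted, which identity fields are captured and how they
#' are weighted during record linkage, the visit schedule, the permitted
#' sample types, the linkage decision thresholds and the backup policy.
#' Configurations live in a single human-editable YAML file so that the
#' study setup is a reviewable artifact.
#'
#' @name study_config
NULL

# Default pseudonym alphabet: A-Z and 2-9 minus the visually ambiguous
# I, O, 0, 1 -- these identifiers are read by humans off printed labels.
DEFAULT_ALPHABET <- "ABCDEFGHJKLMNPQRSTUVWXYZ23456789"

#' Construct a pseudonym format
#'
#' @param prefix short uppercase code identifying the identifier class
#'   (e.g. `"SUB"` for subjects).
#' @param site_code short uppercase site code (e.g. `"BER"`).
#' @param body_length number of generated characters in the identifier body.
#' @param alphabet ordered set of characters the body is drawn from.
#' @param separator single character joining prefix, site, body and check
#'   character.
#' @param check_scheme `"iso7064_mod37_2"` (default) or `"none"`.
#' @param scope `"subject"` or `"biosample"`.
#' @param expected_capacity the number of identifiers the study expects to
#'   issue under this format; validation warns when the identifier space is
#'   not comfortably larger.
#' @return an object of class `pseudonym_format`.
#' @export
pseudonym_format <- function(prefix, site_code, body_length = 6L,
                             alphabet = DEFAULT_ALPHABET, separator = "-",
                             check_scheme = c("iso7064_mod37_2", "none"),
                             scope = c("subject", "biosample"),
                             expected_capacity = 100000L) {
  structure(
    list(
      prefix = as.character(prefix), site_code = as.character(site_code),
      body_length = as.integer(body_length), alphabet = as.character(alphabet),
      separator = as.character(separator),
      check_scheme = match.arg(check_scheme), scope = match.arg(scope),
      expected_capacity = as.numeric(expected_capacity)
    ),
    class = "pseudonym_format"
  )
}

validate_pseudonym_format <- function(fmt, label = fmt$scope) {
  p <- character(0)
  add <- function(msg) p <<- c(p, paste0(label, " format: ", msg))
  if (!is_string(fmt$alphabet) || nchar(fmt$alphabet) < 2L) {
    add("alphabet must contain at least 2 characters")
  } else {
    chars <- strsplit(fmt$alphabet, "")[[1]]
    if (anyDuplicated(chars)) add("alphabet characters must be distinct")
    if (is_string(fmt$separator) && fmt$separator %in% chars) {
      add(paste0("alphabet must not contain the separator '", fmt$separator, "'"))
    }
  }
  if (!is_string(fmt$separator) || nchar(fmt$separator) != 1L) {
    add("separator must be a single character")
  }
  if (!is_count(fmt$body_length)) add("body_length must be a positive integer")
  for (fld in c("prefix", "site_code")) {
    v <- fmt[[fld]]
    if (!is_string(v) || nchar(v) == 0L) {
      add(paste0(fld, " must be non-empty"))
    } else if (is_string(fmt$alphabet) &&
               !all(strsplit(v, "")[[1]] %in% strsplit(fmt$alphabet, "")[[1]])) {
      add(paste0(fld, " '", v, "' uses characters outside the alphabet"))
    }
  }
  if (identical(fmt$check_scheme, "iso7064_mod37_2") && is_string(fmt$alphabet)) {
    iso <- strsplit(ISO7064_SET, "")[[1]]
    bad <- setdiff(strsplit(fmt$alphabet, "")[[1]], iso[iso != "*"])
    if (length(bad)) {
      add(paste0("alphabet characters ", paste(bad, collapse = ", "),
                 " are outside 0-9A-Z required by the iso7064_mod37_2 scheme"))
    }
  }
  p
}

format_space_size <- function(fmt) nchar(fmt$alphabet)^fmt$body_length

#' Construct an identity field schema
#'
#' @param fields a list of field definitions, each a list with elements
#'   `name`, `kind` (`"text"`, `"date"` or `"enum"`), `required` (logical),
#'   `weight` (non-negative linkage weight) and, for enums, `enum_values`.
#' @return an object of class `identity_field_schema`.
#' @export
identity_field_schema <- function(fields) {
  fields <- lapply(fields, function(f) {
    list(
      name = as.character(f$name), kind = as.character(f$kind),
      required = isTRUE(f$required), weight = as.numeric(f$weight %||% 1),
      enum_values = as.character(f$enum_values %||% character(0))
    )
  })
  structure(list(fields = fields), class = "identity_field_schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

schema_field_names <- function(schema) {
  vapply(schema$fields, `[[`, character(1), "name")
}

schema_field <- function(schema, name) {
  for (f in schema$fields) if (identical(f$name, name)) return(f)
  NULL
}

schema_weights <- function(schema) {
  w <- vapply(schema$fields, `[[`, numeric(1), "weight")
  names(w) <- schema_field_names(schema)
  w
}

validate_identity_schema <- function(schema) {
  p <- character(0)
  fs <- schema$fields
  if (!length(fs)) return("identity schema: at least one field is required")
  nm <- schema_field_names(schema)
  if (anyDuplicated(nm)) {
    p <- c(p, paste0("identity schema: duplicate field name(s): ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  kinds <- vapply(fs, `[[`, character(1), "kind")
  bad <- !kinds %in% c("text", "date", "enum")
  if (any(bad)) {
    p <- c(p, paste0("identity schema: unknown kind for field(s): ",
                     paste(nm[bad], collapse = ", ")))
  }
  if (!any(vapply(fs, `[[`, logical(1), "required"))) {
    p <- c(p, "identity schema: at least one field must be required")
  }
  w <- vapply(fs, `[[`, numeric(1), "weight")
  if (any(is.na(w) | w < 0)) {
    p <- c(p, "identity schema: field weights must be non-negative")
  } else if (sum(w) <= 0) {
    p <- c(p, "identity schema: field weights must sum to a positive value")
  }
  for (f in fs) {
    if (identical(f$kind, "enum") && length(f$enum_values) < 1L) {
      p <- c(p, paste0("identity schema: enum field '", f$name,
                       "' needs enum_values"))
    }
  }
  p
}

#' Assemble a study configuration
#'
#' @param subject_format,biosample_format [pseudonym_format()] objects.
#' @param identity_schema an [identity_field_schema()].
#' @param schedule list of visit definitions, each with `visit_id`, `label`,
#'   `order_index` and `allowed_sample_types`.
#' @param sample_types list of `(code, label)` pairs.
#' @param block_threshold,review_threshold linkage decision thresholds in
#'   `[0, 1]`; scores at or above `block_threshold` block a registration,
#'   scores in `[review_threshold, block_threshold)` require manual review.
#' @param backup_interval_days reminder interval for manual export backups.
#' @param rng_seed optional integer seed recorded with the study.
#' @param study_name display name.
#' @return an object of class `study_config`.
#' @export
study_config <- function(subject_format, biosample_format, identity_schema,
                         schedule, sample_types,
                         block_threshold = 0.98, review_threshold = 0.85,
                         backup_interval_days = 1L, rng_seed = NULL,
                         study_name = "STUDY") {
  schedule <- lapply(schedule, function(v) {
    list(
      visit_id = as.character(v$visit_id), label = as.character(v$label),
      order_index = as.integer(v$order_index),
      allowed_sample_types = as.character(v$allowed_sample_types %||% character(0))
    )
  })
  sample_types <- lapply(sample_types, function(s) {
    list(code = as.character(s$code), label = as.character(s$label))
  })
  structure(
    list(
      study_name = as.character(study_name),
      subject_format = subject_format, biosample_format = biosample_format,
      identity_schema = identity_schema, schedule = schedule,
      sample_types = sample_types,
      block_threshold = as.numeric(block_threshold),
      review_threshold = as.numeric(review_threshold),
      backup_interval_days = as.integer(backup_interval_days),
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "study_config"
  )
}

#' Validate a study configuration
#'
#' Checks every structural invariant and raises a single validation error
#' listing all violations, never just the first one.
#'
#' @param config a [study_config()].
#' @return `config`, invisibly, when valid.
#' @export
validate_config <- function(config) {
  p <- character(0)
  if (!inherits(config, "study_config")) {
    psn_stop("pseudoreg_validation_error", "not a study_config object")
  }
  p <- c(p, validate_pseudonym_format(config$subject_format, "subject"))
  p <- c(p, validate_pseudonym_format(config$biosample_format, "biosample"))
  if (!identical(config$subject_format$scope, "subject")) {
    p <- c(p, "subject_format must have scope 'subject'")
  }
  if (!identical(config$biosample_format$scope, "biosample")) {
    p <- c(p, "biosample_format must have scope 'biosample'")
  }
  if (identical(config$subject_format$prefix, config$biosample_format$prefix)) {
    p <- c(p, "subject and biosample formats must use distinct prefixes")
  }
  p <- c(p, validate_identity_schema(config$identity_schema))

  st_codes <- vapply(config$sample_types, `[[`, character(1), "code")
  if (anyDuplicated(st_codes)) {
    p <- c(p, "sample type codes must be unique")
  }
  if (!length(config$schedule)) {
    p <- c(p, "schedule must define at least one visit")
  } else {
    vids <- vapply(config$schedule, `[[`, character(1), "visit_id")
    if (anyDuplicated(vids)) {
      p <- c(p, paste0("duplicate visit_id(s): ",
                       paste(unique(vids[duplicated(vids)]), collapse = ", ")))
    }
    oi <- vapply(config$schedule, `[[`, integer(1), "order_index")
    if (length(oi) > 1L && any(diff(oi) <= 0L)) {
      p <- c(p, "visit order_index values must be strictly increasing")
    }
    for (v in config$schedule) {
      missing <- setdiff(v$allowed_sample_types, st_codes)
      if (length(missing)) {
        p <- c(p, paste0("visit '", v$visit_id, "' allows sample type(s) ",
                         paste(missing, collapse = ", "),
                         " not declared in sample_types"))
      }
    }
  }
  thr_ok <- is.numeric(config$block_threshold) && is.numeric(config$review_threshold) &&
    !is.na(config$block_threshold) && !is.na(config$review_threshold)
  if (!thr_ok || config$block_threshold < 0 || config$block_threshold > 1 ||
      config$review_threshold < 0 || config$review_threshold > 1) {
    p <- c(p, "linkage thresholds must lie in [0, 1]")
  } else if (config$block_threshold < config$review_threshold) {
    p <- c(p, paste0("block_threshold (", config$block_threshold,
                     ") must be >= review_threshold (", config$review_threshold, ")"))
  }
  if (!is_count(config$backup_interval_days)) {
    p <- c(p, "backup_interval_days must be a positive integer")
  }
  if (length(p)) validation_stop(p)

  for (fmt in list(config$subject_format, config$biosample_format)) {
    space <- format_space_size(fmt)
    if (space < fmt$expected_capacity) {
      warning(sprintf(
        "%s format space (%s^%d = %.3g) is below the expected capacity of %s identifiers",
        fmt$scope, "alphabet", fmt$body_length, space,
        format(fmt$expected_capacity, big.mark = ",")
      ), call. = FALSE)
    }
  }
  invisible(config)
}

#' A ready-to-use demonstration configuration
#'
#' Two visits (baseline, follow-up), three sample types, a four-field
#' identity schema (first name, last name, date of birth, sex) and
#' ISO 7064 MOD 37-2 checked pseudonyms for both scopes.
#'
#' @param site_code site code embedded in generated pseudonyms.
#' @return a valid [study_config()].
#' @export
default_config <- function(site_code = "BER") {
  cfg <- study_config(
    study_name = "DEMO",
    subject_format = pseudonym_format("SUB", site_code, scope = "subject"),
    biosample_format = pseudonym_format("SMP", site_code, scope = "biosample"),
    # Linkage weights follow Fellegi-Sunter agreement weights, log2(m/u)
    # with m ~ 0.95: a chance agreement on sex happens half the time
    # (u ~ 0.5, ~1 bit), on a name a few percent of the time (~6 bits) and
    # on a birth date almost never (~8 bits).
    identity_schema = identity_field_schema(list(
      list(name = "first_name", kind = "text", required = TRUE, weight = 6),
      list(name = "last_name", kind = "text", required = TRUE, weight = 6),
      list(name = "date_of_birth", kind = "date", required = TRUE, weight = 8),
      list(name = "sex", kind = "enum", required = TRUE, weight = 1,
           enum_values = c("F", "M", "O"))
    )),
    schedule = list(
      list(visit_id = "BL", label = "Baseline", order_index = 1L,
           allowed_sample_types = c("SER", "PLA", "PBMC")),
      list(visit_id = "FU1", label = "Follow-up 1", order_index = 2L,
           allowed_sample_types = c("SER", "PLA")),
      list(visit_id = "FU2", label = "Follow-up 2", order_index = 3L,
           allowed_sample_types = c("SER"))
    ),
    sample_types = list(
      list(code = "SER", label = "Serum"),
      list(code = "PLA", label = "Plasma"),
      list(code = "PBMC", label = "PBMC")
    )
  )
  validate_config(cfg)
}

# -- YAML (de)serialization ---------------------------------------------------

config_to_list <- function(config) {
  list(
    study_name = config$study_name,
    subject_format = unclass(config$subject_format),
    biosample_format = unclass(config$biosample_format),
    identity_fields = config$identity_schema$fields,
    schedule = config$schedule,
    sample_types = config$sample_types,
    linkage = list(block_threshold = config$block_threshold,
                   review_threshold = config$review_threshold),
    backup_interval_days = config$backup_interval_days,
    rng_seed = config$rng_seed
  )
}

config_from_list <- function(x) {
  need <- c("subject_format", "biosample_format", "identity_fields",
            "schedule", "sample_types")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    psn_stop("pseudoreg_parse_error",
             paste0("config file is missing section(s): ", paste(miss, collapse = ", ")))
  }
  mk_fmt <- function(f, scope) {
    pseudonym_format(
      prefix = f$prefix, site_code = f$site_code,
      body_length = f$body_length %||% 6L,
      alphabet = f$alphabet %||% DEFAULT_ALPHABET,
      separator = f$separator %||% "-",
      check_scheme = f$check_scheme %||% "iso7064_mod37_2",
      scope = f$scope %||% scope,
      expected_capacity = f$expected_capacity %||% 100000L
    )
  }
  study_config(
    study_name = x$study_name %||% "STUDY",
    subject_format = mk_fmt(x$subject_format, "subject"),
    biosample_format = mk_fmt(x$biosample_format, "biosample"),
    identity_schema = identity_field_schema(x$identity_fields),
    schedule = x$schedule,
    sample_types = x$sample_types,
    block_threshold = x$linkage$block_threshold %||% 0.98,
    review_threshold = x$linkage$review_threshold %||% 0.85,
    backup_interval_days = x$backup_interval_days %||% 1L,
    rng_seed = x$rng_seed
  )
}

#' Load and validate a study configuration file
#'
#' @param path path to a YAML configuration file.
#' @return a validated [study_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    psn_stop("pseudoreg_parse_error", paste0("config file not found: ", path))
  }
  x <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) psn_stop("pseudoreg_parse_error",
                                 paste0("cannot parse config file: ",
                                        conditionMessage(e)))
  )
  if (!is.list(x)) psn_stop("pseudoreg_parse_error", "config file is not a mapping")
  validate_config(config_from_list(x))
}

#' Write a study configuration file
#'
#' @param config a [study_config()].
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
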