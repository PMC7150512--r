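# Patient metadata encoding.
#
# ISIC 2019 metadata carries three properties per image: age group (five-year
# steps), anatomical site (eight categories) and sex.  They are encoded as an
# 11-dimensional vector: 8 one-hot site features + 2 one-hot sex features +
# raw age in years.  A missing categorical property zeroes its whole block; a
# missing age is encoded as the sentinel -5, which lies outside the value
# range (age 0 is a legitimate value, so 0 cannot mark missingness).

#' Canonical anatomical site categories
#'
#' The eight ISIC 2019 anatomical sites, in the fixed alphabetical order used
#' for one-hot encoding.
#'
#' @return character vector of length 8.
#' @export
isic_sites <- function() {
  c("anterior torso", "head/neck", "lateral torso", "lower extremity",
    "oral/genital", "palms/soles", "posterior torso", "upper extremity")
}

MISSING_AGE_SENTINEL <- -5

#' Construct a patient metadata record
#'
#' @param age age in years, a non-negative multiple of 5, or `NA`.
#' @param site anatomical site: one of [isic_sites()], a 0-based index into
#'   that vector, or `NA`.
#' @param sex `"female"`, `"male"`, or `NA`.
#' @return an object of class `meta_record`.
#' @export
meta_record <- function(age = NA, site = NA, sex = NA) {
  if (!is.na(age)) {
    abort_if(age < 0 || age %% 5 != 0, "age must be a non-negative multiple of 5")
    age <- as.numeric(age)
  } else age <- NA_real_
  sites <- isic_sites()
  if (!is.na(site)) {
    if (is.numeric(site)) {
      abort_if(!(site %in% 0:7), "site index must be in 0..7")
      site <- sites[site + 1L]
    } else {
      abort_if(!(site %in% sites),
               paste0("unknown site '", site, "'; allowed: ",
                      paste(sites, collapse = ", ")))
    }
  } else site <- NA_character_
  if (!is.na(sex)) {
    abort_if(!(sex %in% c("female", "male")),
             "unknown sex; allowed: female, male")
  } else sex <- NA_character_
  structure(list(age = age, site = site, sex = sex), class = "meta_record")
}

#' Encode a metadata record as an 11-dimensional feature vector
#'
#' Layout: positions 1..8 site one-hot (order of [isic_sites()]), 9..10 sex
#' one-hot (female, male), 11 age in years.  A missing site or sex leaves its
#' block all zero; a missing age becomes the sentinel -5.
#'
#' @param rec a [meta_record()].
#' @return named numeric vector of length 11.
#' @export
encode_metadata <- function(rec) {
  abort_if(!inherits(rec, "meta_record"), "rec must be a meta_record")
  sites <- isic_sites()
  v <- numeric(11)
  names(v) <- c(paste0("site_", seq_len(8)), "sex_female", "sex_male", "age")
  if (!is.na(rec$site)) v[match(rec$site, sites)] <- 1
  if (!is.na(rec$sex)) v[if (rec$sex == "female") 9L else 10L] <- 1
  v[11] <- if (is.na(rec$age)) MISSING_AGE_SENTINEL else rec$age
  v
}

#' Randomly mask metadata properties (training-time augmentation)
#'
#' Independently replaces each of the three properties by missing with
#' probability `p_drop`, so the model learns to tolerate missing values
#' without associating missingness with any class.  Already-missing
#' properties stay missing.  Uses the current RNG state.
#'
#' @param rec a [meta_record()].
#' @param p_drop masking probability in \[0, 1\] (default 0.1).
#' @return a [meta_record()].
#' @export
apply_meta_dropout <- function(rec, p_drop = 0.1) {
  abort_if(!inherits(rec, "meta_record"), "rec must be a meta_record")
  abort_if(p_drop < 0 || p_drop > 1, "p_drop must be in [0, 1]")
  u <- runif(3)
  meta_record(age = if (u[1] < p_drop) NA else rec$age,
              site = if (u[2] < p_drop) NA else rec$site,
              sex = if (u[3] < p_drop) NA else rec$sex)
}

#' Read ISIC-style metadata CSV into meta records
#'
#' Expects columns `image`, `age_approx`, `anatom_site_general`, `sex`;
#' empty cells (or NA) denote missing values.
#'
#' @param path CSV file path, or a data.frame with those columns.
#' @return named list of [meta_record()], keyed by image id.
#' @export
read_isic_metadata <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "age_approx", "anatom_site_general", "sex")
  abort_if(!all(need %in% names(df)),
           paste("metadata must have columns:", paste(need, collapse = ", ")))
  blank_na <- function(x) ifelse(is.na(x) | x == "", NA, x)
  recs <- lapply(seq_len(nrow(df)), function(i)
    meta_record(age = blank_na(df$age_approx[i]),
                site = blank_na(df$anatom_site_general[i]),
                sex = blank_na(df$sex[i])))
  names(recs) <- df$image
  recs
}
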