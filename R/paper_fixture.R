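# Published ETDRS severity distribution of the 1073-eye analyzable set
# (counts per level/modifier) used both as the fixture marginal and as
# the generator's default severity weights.
table2_counts <- function() {
  data.frame(
    base = c(10L, 12L, 14L, 15L, 20L, 35L, 35L, 35L, 35L, 35L, 35L,
             43L, 43L, 47L, 60L, 61L, 61L, 65L, 65L, 71L, 71L, 71L, 90L),
    modifier = c("", "", "B", "", "", "A", "B", "C", "D", "E", "F",
                 "A", "B", "A", "", "A", "B", "A", "B", "A", "C", "D", ""),
    n = c(545L, 95L, 5L, 16L, 137L, 2L, 12L, 57L, 9L, 27L, 106L,
          17L, 19L, 2L, 4L, 5L, 9L, 1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Reconstructed 1073-eye analyzable dataset
#'
#' Rebuilds the analyzable participant-eye set from the published
#' marginal counts: the ETDRS severity distribution (1073 eyes, 275 at
#' base >= 35), 43 DME eyes allocated as 36 at ETDRS < 35 and 7 at
#' ETDRS >= 53 (the unique allocation reconciling 311 DRD-positive and
#' 60 vtDRD eyes with the severity marginal), 567 participants of whom
#' 221 are DRD-positive under the worst-eye rule (90 with both eyes
#' positive, 131 with one). Within-stratum DME placement and the
#' demographic assignment are synthetic: they are fixed by `seed` and
#' match published totals, not individual participants. AI outputs and
#' Level II grades are absent (`NA`) because per-eye outputs were never
#' published.
#'
#' @param demographics If `TRUE`, attach a seeded synthetic demographic
#'   assignment matching the published marginal counts (288 male, 259
#'   Hispanic, 98 Black participants, etc.).
#' @param seed Integer seed for the synthetic within-stratum choices.
#' @return A [trial_dataset()] with 567 participants and 1073 eyes.
#' @export
paper_fixture <- function(demographics = TRUE, seed = 101L) {
  t2 <- table2_counts()
  eyes <- data.frame(
    etdrs_base = rep(t2$base, t2$n),
    etdrs_modifier = rep(t2$modifier, t2$n),
    stringsAsFactors = FALSE
  )
  eyes$dme_level1 <- FALSE
  # 36 DME eyes at ETDRS < 35: placed in the level-20 stratum; 7 at
  # ETDRS >= 53: placed in the 61B stratum. Placement within stratum is
  # arbitrary (only stratum totals are published).
  idx20 <- which(eyes$etdrs_base == 20L)
  eyes$dme_level1[idx20[seq_len(36)]] <- TRUE
  idx61b <- which(eyes$etdrs_base == 61L & eyes$etdrs_modifier == "B")
  eyes$dme_level1[idx61b[seq_len(7)]] <- TRUE
  eyes$cidme <- eyes$dme_level1
  eyes$csdme <- FALSE

  pos <- eyes[order(-eyes$etdrs_base, -eyes$dme_level1), ]
  pos <- pos[is_drd_positive(pos$etdrs_base, pos$dme_level1), ]
  neg <- eyes[!is_drd_positive(eyes$etdrs_base, eyes$dme_level1), ]
  neg <- neg[order(-neg$etdrs_base), ]
  stopifnot(nrow(pos) == 311, nrow(neg) == 762)

  # Participant structure: 90 both-eyes-positive, 131 one-positive
  # (paired with a negative eye), 285 both-negative, 61 single-eye
  # negative -> 567 participants, 221 positive, 1073 eyes.
  pieces <- list(
    data.frame(pid = rep(1:90, each = 2), pos[1:180, ]),
    data.frame(pid = 91:221, pos[181:311, ]),
    data.frame(pid = 91:221, neg[1:131, ]),
    data.frame(pid = rep(222:506, each = 2), neg[132:701, ]),
    data.frame(pid = 507:567, neg[702:762, ])
  )
  df <- do.call(rbind, pieces)
  df <- df[order(df$pid), ]
  df$participant_id <- sprintf("P%03d", df$pid)
  lat <- unlist(lapply(table(df$pid), function(k)
    if (k == 2) c("right", "left") else "right"), use.names = FALSE)
  df$laterality <- lat
  df$pid <- NULL
  rownames(df) <- NULL

  if (demographics) {
    set.seed(seed)
    demo <- data.frame(
      participant_id = sprintf("P%03d", 1:567),
      sex = sample(rep(c("male", "female"), c(288, 279))),
      ethnicity = sample(rep(ethnicity_categories(), c(259, 304, 4))),
      race = sample(rep(c("White", "Black or African American", "Asian",
                          "American Indian or Alaska Native", "Latino",
                          "Native Hawaiian or Other Pacific Islander",
                          "Mixed Race", "Other", "Unknown"),
                        c(385, 98, 35, 13, 22, 6, 5, 2, 1))),
      age = round(pmin(pmax(rnorm(567, 54.1, 12.0), 22), 87), 1),
      hba1c = round(pmin(pmax(rnorm(567, 10.0, 1.99), 4.6), 15.3), 1),
      stringsAsFactors = FALSE
    )
    df <- merge(df, demo, by = "participant_id", sort = FALSE)
  }
  df <- df[order(df$participant_id, df$laterality), ]
  rownames(df) <- NULL
  trial_dataset(df, metadata = list(
    source = "reconstructed from published marginal counts (synthetic pairing)",
    seed = seed))
}
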