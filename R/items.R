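#' Canonical EMA item names
#'
#' The 20 momentary-state items used throughout the package, in the canonical
#' order that indexes every matrix the pipeline produces. Nineteen items are
#' rated on a 1--7 Likert scale; `Being-Alone` is a binary social-context flag
#' (alone = 1, with others = 0). Wellbeing items are stored reverse-coded
#' ("Lacking-..."), so that higher always means worse.
#'
#' @return Character vector of 20 item names.
#' @export
#' @examples
#' ema_item_names()
ema_item_names <- function() {
  c(
    "Lacking-Relaxation",
    "Loneliness",
    "Anxiety",
    "Lacking-Happiness",
    "Irritation",
    "Sensory-Issues",
    "Lacking-Excitement",
    "Sadness",
    "Lacking-Confidence",
    "Feeling-Rejected",
    "Feeling-Unsafe",
    "Confusing-Reality-with-Imagination",
    "Hallucinations",
    "Feeling-Tired",
    "Lacking-Motivation",
    "Lacking-Physical-Activity",
    "Finding-Activity-Difficult",
    "Lacking-Enjoyment",
    "Lacking-Concentration",
    "Being-Alone"
  )
}

#' Map from positively-coded wellbeing item names to reverse-coded names
#'
#' Wellbeing items may arrive positively coded (e.g. `Happiness` on 1--7);
#' at ingest they are reverse-coded (`r' = 8 - r`) and renamed `Lacking-...`.
#'
#' @return Named character vector: positive name -> stored (reverse-coded) name.
#' @export
wellbeing_item_map <- function() {
  c(
    "Happiness"         = "Lacking-Happiness",
    "Relaxation"        = "Lacking-Relaxation",
    "Confidence"        = "Lacking-Confidence",
    "Excitement"        = "Lacking-Excitement",
    "Motivation"        = "Lacking-Motivation",
    "Enjoyment"         = "Lacking-Enjoyment",
    "Concentration"     = "Lacking-Concentration",
    "Physical-Activity" = "Lacking-Physical-Activity"
  )
}

#' Canonical clinical interview (SIPS) item names
#'
#' The 18 SIPS items retained after excluding the rarely endorsed Grandiosity
#' (P3) item: positive (P1, P2, P4, P5), negative (N1--N6), disorganization
#' (D1--D4) and general (G1--G4) symptom items, each scored 0--6.
#'
#' @return Character vector of 18 item names.
#' @export
sips_item_names <- function() {
  c(
    "P1-Unusual-Thought-Content",
    "P2-Persecutory-Ideas",
    "P4-Perceptual-Abnormalities",
    "P5-Disorganized-Communication",
    "N1-Social-Anhedonia",
    "N2-Avolition",
    "N3-Expression-of-Emotion",
    "N4-Experience-of-Emotions",
    "N5-Ideational-Richness",
    "N6-Occupational-Functioning",
    "D1-Odd-Behavior",
    "D2-Bizarre-Thinking",
    "D3-Attention-Trouble",
    "D4-Impaired-Personal-Hygiene",
    "G1-Sleep-Disturbance",
    "G2-Dysphoric-Mood",
    "G3-Motor-Disturbances",
    "G4-Impaired-Stress-Tolerance"
  )
}

# items that may legitimately be binary {0,1} rather than 1-7 Likert
binary_ema_items <- function() "Being-Alone"
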