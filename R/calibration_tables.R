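# Survey-calibrated conditional-probability slices, in percent, as
# published for the three Chongqing community sports parks: for each
# space type, P(interaction level | one direct influence factor).
# Rows are parent states, columns are child levels. Rows are normalized
# on use (the printed percentages carry rounding residue).
#
# These slices parameterize the packaged ground-truth generator
# networks ("paper" effect variant) and back the CPT-export layout.

slice <- function(parent_states, child_states, values) {
  m <- matrix(values, nrow = length(parent_states), byrow = TRUE,
              dimnames = list(parent_states, child_states))
  sweep(m, 1L, rowSums(m), `/`)
}

congregate_levels <- c("very_low", "low", "medium", "high", "very_high")
engagement_levels <- c("low", "medium", "high")

calibration_slices <- list(
  fitness_equipment = list(
    crowds_congregate = list(
      physical_activity = slice(
        c("yes", "no"), congregate_levels,
        c(31.7, 28.4, 19.5, 17.1, 3.3,
          19.3, 23.6, 23.9, 23.9, 9.3)),
      gender = slice(
        c("male", "female"), congregate_levels,
        c(31.4, 27.6, 19.3, 17.9, 3.6,
          19.6, 24.4, 24.1, 23.1, 8.8))),
    engagement = list(
      childrens_play_equipment = slice(
        c("no", "some", "many"), engagement_levels,
        c(31.4, 36.4, 31.4,
          31.4, 33.9, 33.9,
          31.0, 31.0, 37.2)),
      leisure_activity = slice(
        c("yes", "no"), engagement_levels,
        c(29.5, 34.5, 35.3,
          33.3, 33.3, 33.3)),
      age = slice(
        c("<15", "15-25", "26-35", "36-45", "46-55", "56-65", ">65"),
        engagement_levels,
        rep(c(31.4, 33.9, 34.3), 7L)),
      social_relationship = slice(
        c("alone", "general_neighborhood", "familiar_neighborhood",
          "family_friends"), engagement_levels,
        c(33.3, 33.3, 33.3,
          33.3, 33.3, 33.3,
          33.3, 33.3, 33.3,
          25.9, 35.9, 37.6)))),
  path = list(
    crowds_congregate = list(
      visual_obstacles = slice(
        c("0-10", "11-20", "21-27", "28-32"), congregate_levels,
        c(21.4, 19.1, 18.8, 20.0, 20.0,
          25.1, 21.8, 22.3, 20.0, 20.0,
          18.5, 23.6, 20.8, 20.0, 20.0,
          17.6, 18.3, 19.3, 20.0, 20.0)),
      path_width = slice(
        c("narrow", "medium", "wide"), congregate_levels,
        c(19.8, 22.3, 19.5, 19.3, 19.3,
          20.1, 21.2, 22.0, 18.7, 17.9,
          19.7, 22.7, 20.8, 18.6, 18.2)),
      seats_density = slice(
        c("0-5", "6-10", "11-15", "16-25"), congregate_levels,
        c(21.4, 21.0, 19.5, 19.1, 19.1,
          20.0, 20.0, 20.0, 20.0, 20.0,
          18.9, 20.7, 21.8, 19.3, 18.9,
          19.5, 22.6, 21.8, 18.3, 17.9))),
    engagement = list(
      leisure_activity = slice(
        c("yes", "no"), engagement_levels,
        c(33.3, 33.3, 32.3,
          34.7, 34.0, 31.9)),
      seats_density = slice(
        c("0-5", "6-10", "11-15", "16-25"), engagement_levels,
        c(35.0, 33.3, 32.2,
          33.3, 33.3, 33.3,
          32.8, 36.1, 31.2,
          33.1, 35.6, 31.3)),
      vegetation_diversity = slice(
        c("0.2-0.5", "0.6-0.8", "0.9-1.2", "1.3-1.8", "1.8-2.1", "2.2-2.3"),
        engagement_levels,
        c(33.3, 33.3, 33.3,
          35.5, 32.5, 31.5,
          33.5, 35.5, 30.5,
          31.5, 34.5, 33.1,
          33.3, 33.3, 33.3,
          34.7, 33.4, 31.8)),
      social_relationship = slice(
        c("alone", "general_neighborhood", "familiar_neighborhood",
          "family_friends"), engagement_levels,
        c(34.9, 32.9, 32.2,
          34.3, 34.0, 31.1,
          32.7, 35.3, 31.7,
          32.4, 35.4, 31.8)))),
  sports_court = list(
    crowds_congregate = list(
      sports_court = slice(
        c("few", "medium", "many"), congregate_levels,
        c(15.2, 17.6, 24.4, 21.9, 20.8,
          14.0, 21.5, 17.9, 20.1, 19.5,
          17.8, 22.6, 20.5, 17.7, 21.1)),
      age = slice(
        c("<15", "15-25", "26-35", "36-45", "46-55", "56-65", ">65"),
        congregate_levels,
        c(20.0, 20.0, 20.0, 20.0, 20.0,
          29.6, 18.2, 43.5, 33.3, 17.5,
          12.2, 29.8, 26.1, 15.9, 15.9,
          9.8, 19.7, 31.7, 17.8, 20.6,
          14.0, 9.0, 38.5, 21.3, 17.3,
          12.5, 26.5, 16.3, 15.9, 32.7,
          24.9, 24.9, 15.3, 15.3, 15.3))),
    engagement = list(
      physical_activity = slice(
        c("yes", "no"), engagement_levels,
        c(26.9, 36.8, 36.1,
          26.7, 42.9, 30.1)),
      social_relationship = slice(
        c("alone", "general_neighborhood", "familiar_neighborhood",
          "family_friends"), engagement_levels,
        c(32.8, 37.8, 28.8,
          29.1, 37.6, 33.2,
          22.7, 36.9, 40.2,
          22.0, 47.0, 30.3)),
      crowds_congregate = slice(
        congregate_levels, engagement_levels,
        c(42.6, 34.1, 23.2,
          33.8, 40.6, 25.1,
          17.0, 57.9, 25.0,
          18.7, 34.2, 47.0,
          21.9, 32.4, 45.4))))
)
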