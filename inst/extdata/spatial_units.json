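{
  "comment": "Inventory of the 35 spatial study units across the three Chongqing community sports parks. Space type and subtype membership follow the published unit numbering exactly. The park column is a SYNTHETIC stand-in: the study never prints a unit-to-park mapping, so units are assigned to parks in contiguous blocks sized roughly in proportion to park area.",
  "park_assignment": "synthetic",
  "parks": [
    {"name": "Dashuijing", "site_area_m2": 11858, "questionnaires": 124},
    {"name": "Huilongwan", "site_area_m2": 8199, "questionnaires": 133},
    {"name": "Danlong", "site_area_m2": 3803, "questionnaires": 96}
  ],
  "units": [
    {"unit_id": 1,  "space_type": "fitness_equipment", "subtype": "equipment space"},
    {"unit_id": 2,  "space_type": "fitness_equipment", "subtype": "equipment space"},
    {"unit_id": 3,  "space_type": "sports_court",      "subtype": "basketball court"},
    {"unit_id": 4,  "space_type": "sports_court",      "subtype": "badminton court"},
    {"unit_id": 5,  "space_type": "sports_court",      "subtype": "square dancing venue"},
    {"unit_id": 6,  "space_type": "path",              "subtype": "plastic runway"},
    {"unit_id": 7,  "space_type": "path",              "subtype": "recreational trail"},
    {"unit_id": 8,  "space_type": "sports_court",      "subtype": "table tennis court"},
    {"unit_id": 9,  "space_type": "fitness_equipment", "subtype": "children's playground"},
    {"unit_id": 10, "space_type": "fitness_equipment", "subtype": "equipment space"},
    {"unit_id": 11, "space_type": "fitness_equipment", "subtype": "children's playground"},
    {"unit_id": 12, "space_type": "fitness_equipment", "subtype": "equipment space"},
    {"unit_id": 13, "space_type": "sports_court",      "subtype": "badminton court"},
    {"unit_id": 14, "space_type": "fitness_equipment", "subtype": "equipment space"},
    {"unit_id": 15, "space_type": "sports_court",      "subtype": "table tennis court"},
    {"unit_id": 16, "space_type": "sports_court",      "subtype": "table tennis court"},
    {"unit_id": 17, "space_type": "sports_court",      "subtype": "table tennis court"},
    {"unit_id": 18, "space_type": "sports_court",      "subtype": "badminton court"},
    {"unit_id": 19, "space_type": "sports_court",      "subtype": "basketball court"},
    {"unit_id": 20, "space_type": "path",              "subtype": "plastic runway"},
    {"unit_id": 21, "space_type": "path",              "subtype": "plastic runway"},
    {"unit_id": 22, "space_type": "path",              "subtype": "recreational trail"},
    {"unit_id": 23, "space_type": "path",              "subtype": "recreational trail"},
    {"unit_id": 24, "space_type": "fitness_equipment", "subtype": "equipment space"},
    {"unit_id": 25, "space_type": "fitness_equipment", "subtype": "equipment space"},
    {"unit_id": 26, "space_type": "fitness_equipment", "subtype": "children's playground"},
    {"unit_id": 27, "space_type": "sports_court",      "subtype": "table tennis court"},
    {"unit_id": 28, "space_type": "sports_court",      "subtype": "table tennis court"},
    {"unit_id": 29, "space_type": "sports_court",      "subtype": "basketball court"},
    {"unit_id": 30, "space_type": "sports_court",      "subtype": "badminton court"},
    {"unit_id": 31, "space_type": "path",              "subtype": "plastic runway"},
    {"unit_id": 32, "space_type": "path",              "subtype": "plastic runway"},
    {"unit_id": 33, "space_type": "path",              "subtype": "recreational trail"},
    {"unit_id": 34, "space_type": "path",              "subtype": "recreational trail"},
    {"unit_id": 35, "space_type": "path",              "subtype": "recreational trail"}
  ],
  "park_blocks": {"Dashuijing": [1, 13], "Huilongwan": [14, 26], "Danlong": [27, 35]}
}
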