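{
  "version": "1.0",
  "life_stages": ["considering_pregnancy", "currently_pregnant", "child_at_home"],
  "questions": [
    {
      "qid": "Q1",
      "domain_key": "life_stage",
      "prompts": {
        "default": "Are you considering pregnancy, currently pregnant, or have a baby or young children at home?"
      },
      "options": [
        {"option_id": "considering_pregnancy", "text": "I’m considering pregnancy", "score_kind": "na"},
        {"option_id": "currently_pregnant", "text": "I’m currently pregnant", "score_kind": "na"},
        {"option_id": "child_at_home", "text": "I have a baby or young children at home", "score_kind": "na"}
      ]
    },
    {
      "qid": "Q2",
      "domain_key": "location",
      "prompts": {
        "default": "Where do you live? Enter your zipcode. This is to help determine risk of air pollution and lead exposure in your area."
      },
      "options": []
    },
    {
      "qid": "Q3",
      "domain_key": "tobacco",
      "prompts": {
        "default": "How often are you exposed to tobacco or other smoke?"
      },
      "options": [
        {"option_id": "never_public", "text": "Never, or only by passing smokers outdoors in public places", "score_kind": "raw", "raw_score": 10},
        {"option_id": "few_times_week", "text": "Sometimes, I’m around smokers a few times a week, mostly outdoors", "score_kind": "raw", "raw_score": 6},
        {"option_id": "home_smoker", "text": "Frequently, someone in my home smokes", "score_kind": "raw", "raw_score": 3},
        {"option_id": "daily_smoker", "text": "Daily, I smoke", "score_kind": "raw", "raw_score": 1}
      ]
    },
    {
      "qid": "Q4",
      "domain_key": "cleaning",
      "prompts": {
        "considering_pregnancy": "How often are you exposed to conventional cleaning products (consider home and at work)?",
        "currently_pregnant": "How often are you exposed to conventional cleaning products (consider home and at work)?",
        "child_at_home": "How often are conventional cleaning products used in your home?"
      },
      "options": [
        {"option_id": "green_only", "text": "Almost never, I only use “green” products with minimal chemical ingredients", "score_kind": "raw", "raw_score": 9},
        {"option_id": "weekly", "text": "Weekly, or a few times a month", "score_kind": "raw", "raw_score": 6},
        {"option_id": "daily", "text": "Daily, or a few times a week", "score_kind": "raw", "raw_score": 2}
      ]
    },
    {
      "qid": "Q5",
      "domain_key": "pesticides",
      "prompts": {
        "default": "How often are pesticides sprayed in or around your home or building?"
      },
      "options": [
        {"option_id": "never_rarely", "text": "Never or rarely", "score_kind": "raw", "raw_score": 9},
        {"option_id": "sometimes_unsure", "text": "Sometimes, or I’m not sure", "score_kind": "raw", "raw_score": 5},
        {"option_id": "regularly", "text": "Regularly, monthly or more frequently", "score_kind": "raw", "raw_score": 1}
      ]
    },
    {
      "qid": "Q6",
      "domain_key": "plastics",
      "prompts": {
        "considering_pregnancy": "How often do you drink from, eat from, or heat food or drink in plastic containers?",
        "currently_pregnant": "How often do you drink from, eat from, or heat food or drink in plastic containers?",
        "child_at_home": "How often does your child drink or eat from plastic containers, drink or eat items heated in plastic, or chew on plastic toys?"
      },
      "options": [
        {"option_id": "almost_never", "text": "Almost never", "score_kind": "raw", "raw_score": 10},
        {"option_id": "few_month", "text": "A few times a month", "score_kind": "raw", "raw_score": 7},
        {"option_id": "few_week", "text": "A few times a week", "score_kind": "raw", "raw_score": 3},
        {"option_id": "daily", "text": "Daily", "score_kind": "raw", "raw_score": 1}
      ]
    },
    {
      "qid": "Q7",
      "domain_key": "produce",
      "prompts": {
        "default": "How often do you buy organic produce for you or your family, or check the pesticide level on the DirtyDozen list?"
      },
      "options": [
        {"option_id": "always_dirtydozen", "text": "Always, or at least the ones recommended by DirtyDozen", "score_kind": "raw", "raw_score": 9},
        {"option_id": "sometimes", "text": "Sometimes", "score_kind": "raw", "raw_score": 5},
        {"option_id": "never_cheapest", "text": "Never, I buy what’s available or cheapest", "score_kind": "raw", "raw_score": 2}
      ]
    },
    {
      "qid": "Q8",
      "domain_key": "product_volume",
      "prompts": {
        "default": "Roughly how many personal care products do you use on a daily basis? Walk through your day and count them up, consider body and hair wash, other cleansers, toothpaste, skin and hair products, deodorant, cosmetics, nail products, etc."
      },
      "options": [
        {"option_id": "under_10", "text": "Less than 10", "score_kind": "modifier", "raw_score": 9},
        {"option_id": "ten_to_18", "text": "10–18", "score_kind": "modifier", "raw_score": 5},
        {"option_id": "over_18", "text": ">18", "score_kind": "modifier", "raw_score": 1}
      ]
    },
    {
      "qid": "Q9",
      "domain_key": "ingredient_check",
      "prompts": {
        "default": "How often do you check the ingredients of your or your child’s personal care products on a tool like SkinDeep, Think Dirty, or Clearya?"
      },
      "options": [
        {"option_id": "all_the_time", "text": "All the time, for all the products I can", "score_kind": "matrix"},
        {"option_id": "sometimes", "text": "Sometimes", "score_kind": "matrix"},
        {"option_id": "never", "text": "Never", "score_kind": "matrix"}
      ]
    }
  ],
  "lead_bands": {
    "thresholds": [41.05, 50.3, 58.8, 69.3],
    "scores": [9, 7, 5, 3, 1]
  },
  "air_bands": {
    "thresholds": [12, 15],
    "scores": [9, 5, 1]
  },
  "modifier_matrix": {
    "all_the_time": {"9": 10, "5": 7, "1": 5},
    "sometimes": {"9": 8, "5": 6, "1": 3},
    "never": {"9": 7, "5": 3, "1": 1}
  }
}
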