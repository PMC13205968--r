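{
  "lead": {
    "canonical": true,
    "template": "There might be a risk of lead exposure in your home. Consider testing your tap water, and look into ways to reduce lead in the home. Get recommendations here ({factsheet_url})."
  },
  "air": {
    "canonical": false,
    "template": "Air quality in your county can vary day to day. Consider checking the air quality index before long outdoor activity, ventilating while cooking, and using a filter at home if you can. Get more recommendations here ({factsheet_url})."
  },
  "tobacco": {
    "canonical": false,
    "template": "Reducing time around tobacco smoke is one of the most protective steps for your household. Consider asking visitors to smoke outside, and explore supports for cutting back or quitting if you smoke. Get more recommendations here ({factsheet_url})."
  },
  "cleaning": {
    "canonical": false,
    "template": "Consider swapping a few everyday cleaning products for fragrance-free or third-party-certified alternatives, and open a window while you clean. Get more recommendations here ({factsheet_url})."
  },
  "pesticides": {
    "canonical": false,
    "template": "Consider non-chemical pest prevention first, like sealing entry points and storing food in closed containers, and ask about integrated pest management where you live. Get more recommendations here ({factsheet_url})."
  },
  "plastics": {
    "canonical": true,
    "template": "Try to reduce ingestion of plastics. Avoid heating food or drinks in plastic, and switch to metal, glass or other materials for products where possible. Get more recommendations here ({factsheet_url})."
  },
  "produce": {
    "canonical": false,
    "template": "When it fits your budget, consider choosing organic versions of the produce your family eats most often, and rinse all produce well before eating. Get more recommendations here ({factsheet_url})."
  },
  "personal_care": {
    "canonical": true,
    "template": "Keep trying to reduce the number of personal care products you use daily, or check their ingredients and swap out for safer products based on your priorities. Get more recommendations here ({factsheet_url})."
  }
}
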