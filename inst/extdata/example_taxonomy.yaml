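# Small worked-example taxonomy (synthetic): two top-level categories with
# three keyword-defined subcategory searches in English and French. The
# reference taxonomy this mirrors has 5 categories and 35 subcategories;
# its keyword lists are not public, so these queries are illustrative.
expected_categories: 2
expected_subcategories: 3
categories:
  - The Treatment
  - The Illness
subcategories:
  - id: treatment-vaccines
    category: The Treatment
    name: Vaccines
    query:
      en: covid AND (vaccine OR vaccin* OR jab OR "immunization campaign") NOT influenza
      fr: covid AND (vaccin* OR "campagne de vaccination") NOT grippe
  - id: illness-symptoms
    category: The Illness
    name: Confirmed Symptoms
    query:
      en: covid AND (symptom* OR fever OR cough OR "loss of smell")
      fr: covid AND (symptôme* OR fièvre OR toux OR "perte d'odorat")
  - id: illness-transmission
    category: The Illness
    name: Means of Transmission
    query:
      en: covid AND (transmission OR airborne OR droplet* OR "close contact")
      fr: covid AND (transmission OR aérosol* OR "contact étroit")
baseline_words:
  en: [the, and, or, i]
  fr: [le, la, ou, et]
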