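[
  {
    "item_id": "voices",
    "label": "I have been hearing voices",
    "domain_tag": "psychotic",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "voices_distress",
    "label": "The voices have been distressing",
    "domain_tag": "psychotic",
    "branch_parent": "voices",
    "branch_threshold": 2
  },
  {
    "item_id": "suspicious",
    "label": "I have felt suspicious of other people",
    "domain_tag": "psychotic",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "persecution",
    "label": "I have felt that people intend me harm",
    "domain_tag": "psychotic",
    "branch_parent": "suspicious",
    "branch_threshold": 2
  },
  {
    "item_id": "reference",
    "label": "Things around me have carried special messages for me",
    "domain_tag": "psychotic",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "grandiosity",
    "label": "I have felt I have special powers",
    "domain_tag": "psychotic",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "thought_disorder",
    "label": "My thoughts have been jumbled or racing",
    "domain_tag": "psychotic",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "anxious",
    "label": "I have felt anxious",
    "domain_tag": "dysphoric",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "sad",
    "label": "I have felt low in mood",
    "domain_tag": "dysphoric",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "hopeless",
    "label": "I have felt hopeless about the future",
    "domain_tag": "dysphoric",
    "branch_parent": "sad",
    "branch_threshold": 2
  },
  {
    "item_id": "stressed",
    "label": "I have felt stressed or under pressure",
    "domain_tag": "dysphoric",
    "branch_parent": null,
    "branch_threshold": 2
  },
  {
    "item_id": "sleep",
    "label": "I have slept badly",
    "domain_tag": "dysphoric",
    "branch_parent": null,
    "branch_threshold": 2
  }
]
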