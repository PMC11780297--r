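# Editable tailored-message bank. Ids are referenced by the rule set;
# texts are paraphrased heart-failure self-care advice plus placeholder
# general-education fillers.
messages:
  msg_med_benefit_1: >-
    Taking your water pills as prescribed helps remove extra fluid from
    your body and lowers your risk of a hospital stay.
  msg_med_barrier_1: >-
    If water pills make it hard to leave home, try taking them a few
    hours before you go out, or wait until you are back home.
  msg_diet_barrier_1: >-
    You can flavor food without salt: try pepper, lemon juice, garlic,
    onion powder, or basil.
  msg_selfmon_barrier_1: >-
    Weighing yourself every day may feel unpleasant, but it is the
    quickest way to spot fluid building up in your body.
  msg_efficacy_1: >-
    Following your care team's advice and taking your medications as
    directed are important steps in managing your condition.
  msg_efficacy_2: >-
    Tell your doctor right away if you gain 3 or more pounds in a day,
    notice swelling in your feet or ankles, or find it hard to breathe.
  msg_knowledge_1: >-
    Call your health care provider if you notice shortness of breath when
    lying flat or swelling in your legs or stomach.
  msg_general_1: >-
    Small daily habits add up: weigh yourself, check your blood pressure,
    and take your medications at the same time each day.
  msg_general_2: >-
    A short walk most days of the week helps your heart; build up slowly
    and rest when you need to.
  msg_general_3: >-
    Reading food labels helps you stay under your daily sodium goal.
  msg_general_4: >-
    Keep a list of your medications with you at every appointment.
general_pool:
  - msg_general_1
  - msg_general_2
  - msg_general_3
  - msg_general_4
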