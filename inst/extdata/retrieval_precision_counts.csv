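subcategory,category,tp,tp_retest,n
The Cause - The Cause,The Cause,217,NA,300
The Cause - Further Spread - Stigma,The Cause,260,NA,300
The Cause - Further Spread - Immunity,The Cause,245,NA,300
The Illness - Confirmed Symptoms,The Illness,189,239,300
The Illness - Other Discussed Symptoms,The Illness,141,218,300
The Illness - Asymptomatic,The Illness,300,NA,300
The Illness - Presymptomatic,The Illness,300,NA,300
The Illness - Means of Transmission,The Illness,295,NA,300
The Illness - Protection From Transmission,The Illness,299,NA,300
The Illness - Underlying Conditions,The Illness,238,NA,300
The Illness - Demographics - Sex,The Illness,215,NA,300
The Illness - Demographics - Age,The Illness,215,NA,300
The Illness - Vulnerable People,The Illness,287,NA,300
The Illness - Vulnerable Communities,The Illness,269,NA,300
Treatment - Vaccines,Treatment,300,NA,300
Treatment - Current Treatment,Treatment,144,224,300
Treatment - Research & Development,Treatment,290,NA,300
Treatment - Nonproven Treatment (Nutrition),Treatment,245,NA,300
Treatment - Myths,Treatment,126,221,300
Interventions - Measures in Public Settings,Interventions,243,NA,300
Interventions - Testing,Interventions,280,NA,300
Interventions - Supportive Care - Equipment,Interventions,204,257,300
Interventions - Supportive Care - Health Care,Interventions,289,NA,300
Interventions - Personal Measures,Interventions,298,NA,300
Interventions - Reduction of Movement,Interventions,256,NA,300
Interventions - Protection,Interventions,276,NA,300
Interventions - Technology,Interventions,278,NA,300
Interventions - Travel,Interventions,250,NA,300
Interventions - Faith,Interventions,201,269,300
Interventions - Unions and Industry,Interventions,223,NA,300
Interventions - The Environment,Interventions,183,290,300
Interventions - Inequalities,Interventions,280,NA,300
Interventions - Civil Unrest,Interventions,280,NA,300
Information - Misinformation,Information,273,NA,300
Information - Statistics,Information,244,NA,300
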