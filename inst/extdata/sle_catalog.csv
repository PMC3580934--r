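item_id,label_table1,label_table2,domain,mean,weight
death_parents_spouse_siblings,"Death of parents, spouse, or siblings","Death of parents, spouse, or siblings",Loss and separation,0.21,46
childrens_separation_from_family,Children's separation from family,Children's separation from family,Loss and separation,0.29,32
participation_major_examinations,Participation major examinations,Participation of major examinations,Educational concerns,0.31,31
low_income,Low income,Low income,Financial problems,2.06,30
long_lasting_unemployment,Long-lasting unemployment,Long-lasting unemployment,Job security,0.34,29
being_accused,Being accused,Being accused,Home life,0.29,28
educational_problems_of_children,Educational problems of children,Educational problems of children,Educational concerns,0.43,27
major_disease_family_hospitalization,Major disease of family members leading to hospitalization,Major disease of family members leading to hospitalization,Loss and separation,0.68,27
concern_about_job_future,Concern about job future,Concern about job future,Job security,1.00,26
major_financial_problems,Major financial problems,Major financial problems,Financial problems,1.08,24
unwanted_pregnancy,Unwanted pregnancy,Unwanted pregnancy,Sexual life,0.05,22
lack_of_social_support,Lack of social support,Lack of social support,Personal conflicts,0.79,21
failure_in_major_examinations,Failure in major examinations,Failure in major examinations,Educational concerns,0.18,21
failure_achieving_life_goals,Failure in achieving the life goals,Failure in achieving the life goals,Personal conflicts,1.04,19
low_salary,Low salary,Low salary,Job security,1.08,19
major_physical_disease_hospitalization,Major physical disease leading to hospitalization,Major physical disease leading to hospitalization,Health concerns,0.32,19
high_responsibility_job,High responsibility job,High responsibility job,Job security,1.04,18
concern_about_your_future,Concern about your future,Concern about your future,Social relations,1.34,17
not_having_intimate_friend,Not having an intimate friend,Not having an intimate friend,Personal conflicts,0.50,17
job_layoff,Job layoff,Job layoff,Job security,0.53,16
birth_of_a_child,Birth of a child,Birth of a child,Sexual life,0.21,16
addiction_self_or_family,Addiction (self or family member),Addiction (self or family member),Home life,0.18,15
legal_problems,Legal problems,Legal problems,Home life,0.24,14
sexual_relationship_problems,Sexual relationship problems,Sexual relationship problems,Sexual life,0.12,14
troubles_with_children,Troubles with children,Troubles with children,Home life,0.50,13
quarrels_with_spouse,Quarrels with spouse,Quarrels with spouse,Home life,0.31,12
mild_illness,Mild illness,Mild illness,Health concerns,1.00,12
divorce_or_separation,Divorce or separation,Divorce or separation,Home life,0.05,11
financial_inflation,Financial inflation,Financial inflation,Financial problems,2.46,11
dealing_with_customers,Dealing with customers,Dealing with customers,Job conflicts,0.50,11
pregnancy,Pregnancy,Pregnancy,Sexual life,0.08,11
major_social_changes,Major social changes,Major social changes,Social relations,0.77,10
death_close_family_member,Death of a close family member,Death of close family member,Loss and separation,0.81,10
changes_sleeping_eating_habits,Major changes in sleeping and eating habits,Major changes in sleeping and eating habits,Daily life,0.71,10
social_insecurity,Social insecurity,Social insecurity,Social relations,1.01,9
air_pollution_and_traffic,Air pollution and traffic,Air pollution and traffic,Daily life,0.62,7
cultural_alienation,Cultural alienation,Cultural alienation,Personal conflicts,0.65,6
quarrel_with_colleagues_boss,Quarrel with colleagues/boss,Quarrel with colleagues/boss,Job conflicts,0.27,6
improper_working_place,Improper working place and environment,Improper working place and environment,Job conflicts,0.39,5
get_into_debt,Get into debt,Get into debt,Financial problems,1.69,4
high_educational_expenses,High educational expenses,High educational expenses,Educational concerns,0.50,4
taking_on_a_mortgage,Taking on a mortgage,Taking on a mortgage,Financial problems,0.96,3
social_discrimination,Social discrimination,Social discrimination,Social relations,1.15,3
loneliness,Loneliness,Loneliness,Personal conflicts,0.86,3
concern_addiction_family_member,Concern about addiction of a family members,Concern about addiction of a family members,Home life,0.45,1
increased_working_hours,Increased working hours,Increased working hours,Job conflicts,0.44,1
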